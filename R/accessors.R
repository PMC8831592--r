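## Accessors and show methods for the S4 containers.

#' @name accessors
#' @title Accessor functions
#' @description Slot accessors for the package's S4 containers.
#' @param object an object of the documented class
NULL

#' @rdname accessors
#' @export
setGeneric("rfSamples", function(object) standardGeneric("rfSamples"))
#' @rdname accessors
#' @export
setMethod("rfSamples", "RFFrame", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("frameGeometry", function(object) standardGeneric("frameGeometry"))
#' @rdname accessors
#' @export
setMethod("frameGeometry", "RFFrame", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("framePulse", function(object) standardGeneric("framePulse"))
#' @rdname accessors
#' @export
setMethod("framePulse", "RFFrame", function(object) object@pulse)

#' @rdname accessors
#' @export
setGeneric("frameTruth", function(object) standardGeneric("frameTruth"))
#' @rdname accessors
#' @export
setMethod("frameTruth", "RFFrame", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "ParametricImage", function(object) object@channels)

#' @rdname accessors
#' @export
setGeneric("coreMask", function(object) standardGeneric("coreMask"))
#' @rdname accessors
#' @export
setMethod("coreMask", "ParametricImage", function(object) object@coreMask)

#' @rdname accessors
#' @export
setGeneric("marginMask", function(object) standardGeneric("marginMask"))
#' @rdname accessors
#' @export
setMethod("marginMask", "ParametricImage", function(object) object@marginMask)

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setMethod("pixelPitch", "ParametricImage", function(object) object@pixelPitch)

#' @rdname accessors
#' @export
setGeneric("inputTensor", function(object) standardGeneric("inputTensor"))
#' @rdname accessors
#' @export
setMethod("inputTensor", "NetworkInput", function(object) object@tensor)

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "SyntheticCohort", function(object) object@patients)

#' @rdname accessors
#' @export
setGeneric("responseLabel", function(object) standardGeneric("responseLabel"))
#' @rdname accessors
#' @export
setMethod("responseLabel", "PatientRecord", function(object) object@label)

#' Cohort response labels
#'
#' @param cohort a [SyntheticCohort-class]
#' @return named character vector of per-patient labels.
#' @export
cohortLabels <- function(cohort) {
  vapply(cohort@patients, function(p) p@label, character(1)) |>
    stats::setNames(vapply(cohort@patients, function(p) p@patientId,
                           character(1)))
}

#' Cohort survival records
#'
#' @param cohort a [SyntheticCohort-class]
#' @return data.frame with patientId, time (months), event, group label.
#' @export
cohortSurvival <- function(cohort) {
  data.frame(
    patientId = vapply(cohort@patients, function(p) p@patientId, character(1)),
    time = vapply(cohort@patients, function(p) p@survivalMonths, numeric(1)),
    event = vapply(cohort@patients, function(p) p@event, logical(1)),
    group = vapply(cohort@patients, function(p) p@label, character(1)))
}

setMethod("show", "RFFrame", function(object) {
  g <- object@geometry
  cat(sprintf("RFFrame: %d lines x %d samples (%.1f x %.1f mm), fs = %g MHz\n",
              g@nLines, g@nSamples, g@nLines * g@lateralPitch,
              g@nSamples * g@axialPitch, object@pulse@samplingFrequency))
})

setMethod("show", "ParametricImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf(
    "ParametricImage: %d x %d px @ %.3g mm (%s); core %d px, margin %d px\n",
    d[1], d[2], object@pixelPitch, paste(qusChannels(), collapse = ","),
    sum(object@coreMask), sum(object@marginMask)))
})

setMethod("show", "SyntheticCohort", function(object) {
  lab <- vapply(object@patients, function(p) p@label, character(1))
  cat(sprintf("SyntheticCohort: %d patients (%d responders, %d non-responders), seed %d\n",
              length(lab), sum(lab == "responder"),
              sum(lab == "non-responder"), object@seed))
})

setMethod("show", "QusEstimate", function(object) {
  cat(sprintf("QusEstimate: MBF %.2f dB, SS %.2f dB/MHz, SI %.2f dB, ESD %.1f um, EAC %.2f dB\n",
              object@mbf, object@ss, object@si, object@esd, object@eac))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult %s: p(responder) = %.3f, p(non-responder) = %.3f -> %s\n",
              object@patientId, object@pResponder, object@pNonResponder,
              object@predictedLabel))
})
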