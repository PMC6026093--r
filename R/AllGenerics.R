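#' Accessors for package classes
#'
#' Small generic accessors: number of samples/channels, signal data matrix,
#' sampling rate, channel names, spectral radius of an MVAR companion matrix.
#'
#' @param x an object of one of the package classes.
#' @return The corresponding slot value (or derived scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' @rdname accessors
#' @export
setMethod("signalData", "EEGSignal", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGSignal", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGSignal", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("nSamples", "EEGSignal", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nChannels", "EEGSignal", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("channelNames", "MVARModel", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("nChannels", "MVARModel", function(x) length(x@channelNames))
#' @rdname accessors
#' @export
setMethod("samplingRate", "MVARModel", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("channelNames", "ConnectivityTensor", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("nChannels", "ConnectivityTensor", function(x) length(x@channelNames))

#' @rdname accessors
#' @export
setMethod("channelNames", "PsiEstimate", function(x) x@channelNames)

#' Spectral radius of the companion matrix of an MVAR model
#'
#' The model is stationary (stable) iff the spectral radius is strictly
#' below 1.
#'
#' @param x an [MVARModel-class].
#' @return Largest eigenvalue modulus of the block companion matrix.
#' @export
setMethod("spectralRadius", "MVARModel", function(x) {
  nc <- nChannels(x)
  m <- x@order
  comp <- matrix(0, nc * m, nc * m)
  for (r in seq_len(m))
    comp[seq_len(nc), (r - 1L) * nc + seq_len(nc)] <- x@A[[r]]
  if (m > 1L)
    comp[nc + seq_len(nc * (m - 1L)), seq_len(nc * (m - 1L))] <-
      diag(nc * (m - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
})

setMethod("show", "EEGSignal", function(object) {
  cat(sprintf("EEGSignal: %d samples x %d channels @ %g Hz (%.3f s)%s\n",
              nSamples(object), nChannels(object), samplingRate(object),
              nSamples(object) / samplingRate(object),
              if (object@isNormalized) ", normalized [0,1]" else ""))
  cat("channels:", paste(channelNames(object), collapse = ", "), "\n")
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: order %d, %d channels, spectral radius %.3f\n",
              object@order, nChannels(object), spectralRadius(object)))
})

setMethod("show", "ConnectivityTensor", function(object) {
  cat(sprintf("ConnectivityTensor [%s]: %d x %d channels, %d frequencies (%g-%g Hz)\n",
              object@method, nChannels(object), nChannels(object),
              length(object@freqs), min(object@freqs), max(object@freqs)))
})

setMethod("show", "PsiEstimate", function(object) {
  cat(sprintf("PsiEstimate: band [%g, %g] Hz, %d channels, k1 = %d segments\n",
              object@band[1], object@band[2], length(object@channelNames),
              object@segmentCount))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: PSS %d (%s), %d conditions\n",
              object@subjectId, object@pssScore, object@stressGroup,
              length(object@signals)))
})
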