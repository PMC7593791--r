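#' The 90-region AAL cortical/subcortical atlas labels
#'
#' Returns the standard abbreviations of the 90 regions of the Automated
#' Anatomical Labeling atlas in the conventional interleaved order
#' (left hemisphere on odd positions, right on even: `PreCG.L`, `PreCG.R`,
#' `SFGdor.L`, ...).  These labels name the nodes of every network built by
#' the package and are the label set expected in time-series file headers.
#'
#' @return Character vector of length 90, unique region abbreviations.
#' @export
#' @examples
#' length(aal90_labels())
#' grep("INS|STG", aal90_labels(), value = TRUE)
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

#' Construct a region atlas
#'
#' A region atlas is an ordered set of unique region names defining the node
#' order of all matrices in an analysis.  Internally nodes are addressed by
#' position (1-based, as usual in R); reports use the label strings.
#'
#' @param labels Character vector of unique region names.  Defaults to the
#'   90 AAL labels from [aal90_labels()].
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(labels = aal90_labels()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("atlas labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(labels) < 3L) stop("an atlas needs at least 3 regions")
  structure(list(labels = labels, n = length(labels)), class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", x$n, " regions: ",
      paste(utils::head(x$labels, 4), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' @export
length.region_atlas <- function(x) x$n

# resolve labels to 1-based indices, with a clear error on unknowns
atlas_index <- function(atlas, labels) {
  idx <- match(labels, atlas$labels)
  if (anyNA(idx)) {
    stop("unknown region label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}
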