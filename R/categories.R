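#' Tissue categories used throughout the pipeline
#'
#' The classification stage distinguishes ten tissue categories. Six of them
#' (the five soft organs plus bone) are carried through to the final
#' segmentation; the remaining four act as "context" classes that absorb
#' tissue the extractor is not asked to produce.
#'
#' @return Character vector of the ten category names, in the fixed order
#'   used for integer label encoding (label \code{i} is
#'   \code{dce_categories()[i]}; 0 is background).
#' @export
dce_categories <- function() {
  c("heart", "liver", "spleen", "lung", "kidney", "bone",
    "intestinal_wall", "intestinal_cavity", "fat_muscle", "skin_adherent")
}

#' Organs extracted into the final segmentation
#'
#' @return Character vector of the six organ categories that receive a final
#'   binary mask, in default priority order (highest priority first): a voxel
#'   claimed by several organs goes to the earliest one in this order.
#' @export
dce_organs <- function() {
  c("bone", "kidney", "lung", "liver", "heart", "spleen")
}

category_id <- function(name) {
  id <- match(name, dce_categories())
  if (anyNA(id)) {
    stop("unknown category: ", paste(name[is.na(id)], collapse = ", "))
  }
  id
}
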