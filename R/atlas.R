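#' Packaged 112-region atlas table
#'
#' A Harvard-Oxford-style label table (48 cortical regions per hemisphere
#' plus 8 subcortical structures per hemisphere, 112 rows; a constructed
#' stand-in, see the file name) merged with the packaged MNI node
#' coordinates for the regions shared by the static and dynamic
#' expression-discriminative networks. Regions without a packaged
#' coordinate carry `NA`.
#'
#' For parcellations of a different size, synthetic `ROI_###` labels are
#' generated.
#'
#' @param n_rois Number of regions (112 loads the packaged table).
#' @return Tibble with columns `roi_index` (0-based), `hemisphere`,
#'   `label`, `mni_x`, `mni_y`, `mni_z`.
#' @export
atlas_table <- function(n_rois = 112) {
  if (n_rois != 112) {
    return(tibble::tibble(roi_index = seq_len(n_rois) - 1L,
                          hemisphere = NA_character_,
                          label = sprintf("ROI_%03d", seq_len(n_rois)),
                          mni_x = NA_real_, mni_y = NA_real_,
                          mni_z = NA_real_))
  }
  labels <- readr::read_tsv(
    system.file("extdata", "roi_labels_112_synthetic.tsv",
                package = "fcdecoder"),
    show_col_types = FALSE, progress = FALSE)
  coords <- overlap_node_coordinates()
  key <- function(h, l) paste(h, normalize_label(l))
  m <- match(key(labels$hemisphere, labels$label),
             key(coords$hemisphere, coords$label))
  labels$mni_x <- coords$mni_x[m]
  labels$mni_y <- coords$mni_y[m]
  labels$mni_z <- coords$mni_z[m]
  labels
}

#' Packaged MNI coordinates of the overlap-network nodes
#'
#' The node coordinates of the brain regions involved in both the static
#' and the dynamic expression-discriminative networks, as packaged.
#'
#' @return Tibble with `hemisphere`, `label`, `mni_x`, `mni_y`, `mni_z`.
#' @export
overlap_node_coordinates <- function() {
  readr::read_tsv(
    system.file("extdata", "table1_overlap_nodes_mni.tsv",
                package = "fcdecoder"),
    show_col_types = FALSE, progress = FALSE)
}

#' @keywords internal strip parentheticals, case-fold, for label matching
#' @noRd
normalize_label <- function(x) {
  tolower(trimws(gsub("\\s*\\(.*\\)", "", x)))
}
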