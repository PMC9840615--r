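# segment one stimulus row into its two arrays and the two images used for
# hashing; returns list(seg_a, seg_b, img_a, img_b)
.segment_stimulus <- function(row, pics_dir) {
  if (nzchar(row$file_joint)) {
    colors <- if (row$style == "D4") c("yellow", "blue") else c("red", "blue")
    img <- read_image(file.path(pics_dir, row$file_joint))
    segs <- segment_colors(img, colors)
    list(seg_a = segs[[1]], seg_b = segs[[2]],
         img_a = isolate_mask(segs[[1]]), img_b = isolate_mask(segs[[2]]))
  } else {
    img_a <- read_image(file.path(pics_dir, row$file_a))
    img_b <- read_image(file.path(pics_dir, row$file_b))
    list(seg_a = segment_panel(img_a), seg_b = segment_panel(img_b),
         img_a = img_a, img_b = img_b)
  }
}

#' Extract the feature table for a rendered stimulus set
#'
#' For every stimulus: segments the image(s) into the two dot arrays, counts
#' dots, computes the geometric property ratios (fewer-dot array divided by
#' more-dot array) and the three hash Hamming distances between the two
#' array images (for two-color stimuli, between the two color-isolated
#' views).
#'
#' @param stimlist stimulus-list data frame (see [generate_dataset()]) or
#'   path to a stimulus-list CSV.
#' @param pics_dir directory holding the rendered images.
#' @param phash_literal_8x8 passed to [hash_perceptual()].
#' @param sd_type passed to [array_properties()].
#' @return Data frame with one row per STIMID: `STIMID`, `dot_ratio`, the 12
#'   visual ratio indices, `hash_avg`, `hash_perc`, `hash_wav`, the segmented
#'   counts `n_a_seg`, `n_b_seg`, and `seg_mismatch` (TRUE when the
#'   segmented counts disagree with the stimulus list; also warned).
#' @export
extract_dataset <- function(stimlist, pics_dir, phash_literal_8x8 = FALSE,
                            sd_type = "population") {
  if (is.character(stimlist)) stimlist <- read_stimlist(stimlist)
  rows <- vector("list", nrow(stimlist))
  for (i in seq_len(nrow(stimlist))) {
    row <- stimlist[i, ]
    s <- .segment_stimulus(row, pics_dir)
    props_a <- array_properties(s$seg_a, sd_type)
    props_b <- array_properties(s$seg_b, sd_type)
    hashes <- list(
      hash_avg = hamming(hash_average(s$img_a), hash_average(s$img_b)),
      hash_perc = hamming(hash_perceptual(s$img_a, phash_literal_8x8),
                          hash_perceptual(s$img_b, phash_literal_8x8)),
      hash_wav = hamming(hash_wavelet(s$img_a), hash_wavelet(s$img_b)))
    fv <- suppressWarnings(feature_vector(props_a, props_b, hashes))
    mismatch <- !(identical(props_a$n_dots + 0, row$n_a + 0) &&
                    identical(props_b$n_dots + 0, row$n_b + 0))
    if (mismatch)
      warning(sprintf(
        "%s: segmented counts (%d, %d) differ from stimulus list (%d, %d)",
        row$STIMID, props_a$n_dots, props_b$n_dots, row$n_a, row$n_b))
    rows[[i]] <- data.frame(STIMID = row$STIMID, as.data.frame(fv),
                            n_a_seg = props_a$n_dots,
                            n_b_seg = props_b$n_dots,
                            seg_mismatch = mismatch,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write / read a features CSV
#'
#' @param features feature data frame from [extract_dataset()].
#' @param path CSV file path.
#' @return `read_features` returns the data frame; `write_features` the path,
#'   invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
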