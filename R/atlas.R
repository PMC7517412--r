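## Rearranged 68-region Desikan-Killiany atlas: regions ordered by lobe
## (frontal 1-28, temporal 29-46, parietal 47-60, occipital 61-68) with odd
## indices in the left hemisphere and even indices in the right.

.lobes <- c("frontal", "temporal", "parietal", "occipital")
.lobe_ranges <- list(frontal = 1:28, temporal = 29:46, parietal = 47:60,
                     occipital = 61:68)

## md5 of the packaged transcription; guards against corruption of the data
## file after installation.
.atlas_md5 <- "3696a644db83e5dfa7e8c756c6104ec6"

#' Load the packaged 68-region cortical atlas
#'
#' Returns the rearranged Desikan-Killiany parcellation shipped with the
#' package: 34 regions per hemisphere ordered by lobe, with odd indices in
#' the left hemisphere and even indices in the right (frontal 1-28,
#' temporal 29-46, parietal 47-60, occipital 61-68).
#'
#' @param check_integrity Verify the md5 checksum of the packaged file before
#'   parsing (default `TRUE`).
#' @return An `fd_atlas` data frame with one row per region and columns
#'   `index`, `name`, `abbreviation`, `hemisphere`, `lobe`, and `label`
#'   (abbreviation plus `(L)`/`(R)` suffix, e.g. `"CACg(L)"`).
#' @export
#' @examples
#' atlas <- load_default_atlas()
#' table(atlas$lobe)
load_default_atlas <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "atlas_dk68.csv", package = "fdnet")
  if (!nzchar(path) || !file.exists(path))
    fd_stop("fdnet_integrity_error", "packaged atlas file is missing")
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .atlas_md5))
      fd_stop("fdnet_integrity_error", sprintf(
        "packaged atlas file failed its integrity check (md5 %s, expected %s)",
        md5, .atlas_md5))
  }
  read_atlas(path)
}

#' Read or write an atlas as delimited text
#'
#' One row per region with columns `index`, `name`, `abbreviation`,
#' `hemisphere`, `lobe`. Reading validates the full set of structural
#' invariants (68 regions, 34 per hemisphere, lobe sizes 28/18/14/8,
#' odd = left / even = right pairing, unique abbreviation-hemisphere pairs).
#'
#' @param path Path to a comma-separated atlas file.
#' @param atlas An `fd_atlas` object.
#' @return `read_atlas` returns an `fd_atlas`; `write_atlas` returns `path`,
#'   invisibly.
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_atlas(df)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  atlas <- as_atlas(atlas)
  utils::write.csv(
    atlas[, c("index", "name", "abbreviation", "hemisphere", "lobe")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coerce and validate an atlas data frame
#'
#' @param df A data frame with columns `index`, `name`, `abbreviation`,
#'   `hemisphere`, `lobe`.
#' @return An `fd_atlas` data frame ordered by `index`, with a derived
#'   `label` column.
#' @export
as_atlas <- function(df) {
  need <- c("index", "name", "abbreviation", "hemisphere", "lobe")
  if (!all(need %in% names(df)))
    fd_stop("fdnet_validation_error", paste(
      "atlas table must have columns:", paste(need, collapse = ", ")))
  df <- df[order(df$index), need, drop = FALSE]
  if (nrow(df) != 68 || !identical(as.integer(df$index), 1:68))
    fd_stop("fdnet_validation_error", "atlas must contain regions indexed 1 to 68")
  if (!all(df$hemisphere %in% c("left", "right")) || !all(df$lobe %in% .lobes))
    fd_stop("fdnet_validation_error", "invalid hemisphere or lobe value in atlas")
  odd <- df$index %% 2 == 1
  if (!all(df$hemisphere[odd] == "left") || !all(df$hemisphere[!odd] == "right"))
    fd_stop("fdnet_validation_error",
            "atlas must pair odd indices with the left hemisphere and even with the right")
  for (lb in .lobes) {
    if (!identical(which(df$lobe == lb), .lobe_ranges[[lb]]))
      fd_stop("fdnet_validation_error", sprintf(
        "atlas indices for the %s lobe must be %d-%d", lb,
        min(.lobe_ranges[[lb]]), max(.lobe_ranges[[lb]])))
  }
  key <- paste(df$abbreviation, df$hemisphere)
  if (anyDuplicated(key))
    fd_stop("fdnet_validation_error", "abbreviation-hemisphere pairs must be unique")
  df$label <- paste0(df$abbreviation, "(",
                     ifelse(df$hemisphere == "left", "L", "R"), ")")
  rownames(df) <- NULL
  class(df) <- c("fd_atlas", "data.frame")
  df
}

#' Select region indices by lobe and hemisphere
#'
#' @param atlas An `fd_atlas`.
#' @param lobe One of `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`,
#'   or `"all"`.
#' @param hemisphere One of `"left"`, `"right"`, or `"both"`.
#' @return An integer vector of 1-based region indices matching both filters.
#' @export
#' @examples
#' rois_in(load_default_atlas(), "occipital", "both")
rois_in <- function(atlas, lobe = "all", hemisphere = "both") {
  atlas <- as_atlas(atlas)
  lobe <- match.arg(lobe, c("all", .lobes))
  hemisphere <- match.arg(hemisphere, c("both", "left", "right"))
  keep <- rep(TRUE, 68)
  if (lobe != "all") keep <- keep & atlas$lobe == lobe
  if (hemisphere != "both") keep <- keep & atlas$hemisphere == hemisphere
  atlas$index[keep]
}

#' Map region labels to atlas indices
#'
#' @param labels Character vector of labels such as `"CACg(L)"` (as produced
#'   in the atlas `label` column; matching is case-insensitive).
#' @param atlas An `fd_atlas`.
#' @return Integer vector of region indices.
#' @export
roi_index <- function(labels, atlas = load_default_atlas()) {
  atlas <- as_atlas(atlas)
  idx <- match(tolower(labels), tolower(atlas$label))
  if (anyNA(idx))
    fd_stop("fdnet_validation_error", paste(
      "unknown region label(s):", paste(labels[is.na(idx)], collapse = ", ")))
  atlas$index[idx]
}
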