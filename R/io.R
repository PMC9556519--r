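#' Read / write the participants table
#'
#' BIDS-style tab-separated participants table with columns
#' `participant_id`, `site`, `age`, `sex` and the optional QC score columns
#' `expert_qc_score`, `xgb_qc_score`, `xgb_qsiprep_qc_score`, `dl_qc_score`
#' (all bounded in \[0,1\] when present; missing encoded as `n/a`). Unknown
#' columns are preserved, and a write-then-read round trip reproduces the
#' table.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("n/a", "NA", ""),
                          check.names = FALSE)
  validate_participants(df)
  df
}

#' @param table participants data frame.
#' @rdname read_participants
#' @export
write_participants <- function(table, path) {
  validate_participants(table)
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "n/a")
  invisible(path)
}

qc_score_columns <- function() {
  c("expert_qc_score", "xgb_qc_score", "xgb_qsiprep_qc_score", "dl_qc_score")
}

validate_participants <- function(df) {
  if (!"participant_id" %in% names(df)) {
    stop("participants table must have a participant_id column")
  }
  dup <- which(duplicated(df$participant_id))
  if (length(dup) > 0L) {
    stop("duplicate participant_id at rows: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  for (col in intersect(qc_score_columns(), names(df))) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0L) {
      stop(col, " out of [0,1] at rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  invisible(df)
}

#' Write / read a 4-channel QC volume as NIfTI
#'
#' The four channels (b=0 and the x/y/z DEC-FA components) are stored as the
#' fourth dimension of a 4D NIfTI file.
#'
#' @param volume (D,H,W,4) array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_qc_volume <- function(volume, path) {
  stopifnot(length(dim(volume)) == 4L)
  RNifti::writeNifti(volume, path)
  invisible(path)
}

#' @rdname write_qc_volume
#' @export
read_qc_volume <- function(path) {
  v <- RNifti::readNifti(path)
  arr <- array(as.numeric(v), dim = dim(v))
  if (length(dim(arr)) != 4L) stop("expected a 4D (D,H,W,channels) NIfTI")
  dimnames(arr) <- list(NULL, NULL, NULL,
                        c("b0", "decfa_x", "decfa_y", "decfa_z"))
  arr
}

#' Derive per-stage seeds from a root seed
#'
#' All pipeline randomness flows from one root seed, expanded
#' deterministically into named per-stage seeds that are recorded in output
#' metadata.
#'
#' @param root_seed integer.
#' @param stages character vector of stage names.
#' @return named integer vector.
#' @export
derive_seeds <- function(root_seed, stages) {
  out <- vapply(seq_along(stages), function(i) {
    (as.integer(root_seed) * 1009L + i * 9973L) %% 2147483647L
  }, integer(1))
  stats::setNames(out, stages)
}
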