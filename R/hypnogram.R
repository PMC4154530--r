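#' Construct a hypnogram
#'
#' A hypnogram is the per-night time series of sleep stages, one label per
#' 30-s epoch. Unscored epochs carry the label `"UNKNOWN"`; they are excluded
#' from training and from all reported metrics.
#'
#' @param stages character vector of stage labels (see [SLEEP_STAGES_ALL]).
#' @param epoch_duration_s epoch length in seconds (30 under AASM rules).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_duration_s = 30) {
  stages <- as.character(stages)
  if (length(stages) < 1) stop("a hypnogram needs at least one epoch")
  check_stages(stages)
  if (!is.numeric(epoch_duration_s) || epoch_duration_s <= 0)
    stop("`epoch_duration_s` must be positive")
  structure(list(epoch_duration_s = as.numeric(epoch_duration_s),
                 stages = stages),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES_ALL))
  tab <- tab[tab > 0]
  cat(sprintf("<hypnogram> %d epochs of %g s: %s\n", length(x$stages),
              x$epoch_duration_s,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Read a hypnogram side-car file
#'
#' Accepts either the two-column CSV format written by [write_hypnogram()]
#' (header `epoch,stage`, rows like `0,W`) or a bare one-token-per-line file.
#' The token `?` maps to `"UNKNOWN"`.
#'
#' @param path file path.
#' @param epoch_duration_s epoch length in seconds.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_duration_s = 30) {
  if (!file.exists(path)) stop(sprintf("hypnogram file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("'%s' contains no epochs", path))
  has_csv <- grepl(",", lines[1], fixed = TRUE)
  if (has_csv) {
    body <- lines
    if (grepl("^\\s*epoch\\s*,\\s*stage\\s*$", lines[1], ignore.case = TRUE))
      body <- lines[-1]
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad) > 0)
      stop(sprintf("'%s' line %d: expected `epoch,stage`", path,
                   bad[1] + (length(body) < length(lines))))
    idx <- suppressWarnings(as.integer(trimws(vapply(parts, `[`, "", 1))))
    tok <- toupper(trimws(vapply(parts, `[`, "", 2)))
    if (anyNA(idx))
      stop(sprintf("'%s': non-integer epoch index on line %d", path,
                   which(is.na(idx))[1] + (length(body) < length(lines))))
    if (anyDuplicated(idx))
      stop(sprintf("'%s': duplicate epoch index %d", path,
                   idx[anyDuplicated(idx)]))
    tok <- tok[order(idx)]
  } else {
    tok <- toupper(trimws(lines))
  }
  stages <- ifelse(tok == "?", "UNKNOWN", tok)
  bad <- which(!stages %in% SLEEP_STAGES_ALL)
  if (length(bad) > 0)
    stop(sprintf("'%s': unrecognized stage token '%s' (entry %d)",
                 path, tok[bad[1]], bad[1]))
  hypnogram(stages, epoch_duration_s)
}

#' Write a hypnogram side-car file
#'
#' Writes the two-column CSV format (`epoch,stage`; 0-based epoch indices;
#' `"UNKNOWN"` written as `?`). [read_hypnogram()] round-trips it exactly.
#'
#' @param h a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  tok <- ifelse(h$stages == "UNKNOWN", "?", h$stages)
  writeLines(c("epoch,stage",
               sprintf("%d,%s", seq_along(tok) - 1L, tok)), path)
  invisible(path)
}
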