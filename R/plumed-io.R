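# whitespace-delimited PLUMED-dialect files with a `#! FIELDS ...` header

read_plumed_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- which(startsWith(lines, "#! FIELDS"))
  if (length(hdr_i) == 0) {
    abort(paste("format error: missing '#! FIELDS' header in", path))
  }
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[hdr_i[1]])), "[ \t]+")[[1]]
  body_i <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  body_i <- body_i[body_i > hdr_i[1]]
  if (length(body_i) == 0) {
    return(tibble::as_tibble(setNames(
      replicate(length(fields), numeric(0), simplify = FALSE), fields)))
  }
  rows <- strsplit(trimws(lines[body_i]), "[ \t]+")
  bad <- which(lengths(rows) != length(fields))
  if (length(bad)) {
    abort(sprintf("format error: ragged row at line %d of %s (%d fields, expected %d)",
                  body_i[bad[1]], path, lengths(rows)[bad[1]], length(fields)))
  }
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  tibble::as_tibble(m)
}

write_plumed_table <- function(tb, path, digits = 10) {
  hdr <- paste("#! FIELDS", paste(names(tb), collapse = " "))
  body <- do.call(paste, c(purrr::map(tb, ~ formatC(.x, digits = digits,
                                                    format = "g")),
                           list(sep = " ")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write COLVAR files (PLUMED dialect)
#'
#' COLVAR files hold a `time` column plus CV columns; a `bias` column and any
#' unknown columns are preserved as-is. `write_colvar` emits the trajectory's
#' time (steps), CV columns, and instantaneous bias.
#'
#' @param path File path.
#' @param cv_names CV column names; by default every column except `time`
#'   and `bias`.
#' @return `read_colvar` returns an `ionbind_trajectory` tibble;
#'   `write_colvar` returns `path` invisibly.
#' @export
read_colvar <- function(path, cv_names = NULL) {
  tb <- read_plumed_table(path)
  if (!"time" %in% names(tb)) abort("format error: COLVAR file lacks a time column")
  cv_names <- cv_names %||% setdiff(names(tb), c("time", "bias"))
  out <- tb
  attr(out, "cv_names") <- cv_names
  class(out) <- c("ionbind_trajectory", class(out))
  out
}

#' @rdname read_colvar
#' @param trajectory An `ionbind_trajectory` (e.g. from [run_wtmetad()]).
#' @export
write_colvar <- function(trajectory, path) {
  cvn <- attr(trajectory, "cv_names") %||%
    setdiff(names(trajectory), c("step", "time", "bias",
                                 grep("^x\\d+$", names(trajectory), value = TRUE)))
  time <- if ("time" %in% names(trajectory)) trajectory$time else trajectory$step
  tb <- tibble::tibble(time = time)
  for (cv in cvn) tb[[cv]] <- trajectory[[cv]]
  if ("bias" %in% names(trajectory)) tb$bias <- trajectory$bias
  write_plumed_table(tb, path)
}

#' Read / write HILLS files (PLUMED dialect)
#'
#' HILLS files hold one deposited Gaussian per row:
#' `time <centers> <sigma_...> height biasf`.
#'
#' @param path File path.
#' @return `read_hills` returns a [bias_state()]; `write_hills` returns
#'   `path` invisibly.
#' @export
read_hills <- function(path) {
  tb <- read_plumed_table(path)
  if (!"time" %in% names(tb)) abort("format error: HILLS file lacks a time column")
  sig <- grep("^sigma_", names(tb), value = TRUE)
  cvn <- sub("^sigma_", "", sig)
  if (length(cvn) == 0 || !all(cvn %in% names(tb))) {
    abort("format error: HILLS file lacks matched cv/sigma_cv columns")
  }
  gamma <- if ("biasf" %in% names(tb) && nrow(tb)) tb$biasf[1] else 5
  bias_state(tb, gamma = gamma, cv_names = cvn)
}

#' @rdname read_hills
#' @param bias A [bias_state()].
#' @export
write_hills <- function(bias, path) {
  cvn <- attr(bias, "cv_names")
  tb <- bias[, c("time", cvn, paste0("sigma_", cvn), "height"), drop = FALSE]
  tb$biasf <- if ("biasf" %in% names(bias)) bias$biasf else attr(bias, "gamma")
  write_plumed_table(tibble::as_tibble(tb), path)
}
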