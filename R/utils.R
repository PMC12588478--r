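# internal helpers shared across modules

# all derived seeds stay below 2^31 - 1 (R integer range)
.seedCap <- 2147480000

.deriveSeed <- function(base, ...) {
  parts <- c(...)
  h <- 0
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 31 + as.numeric(p)) %% 1e9
  }
  as.integer((as.numeric(base) + h * 7919) %% .seedCap)
}

.assertScalarCount <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("invalid '%s': must be a positive count", field), call. = FALSE)
  invisible(as.integer(x))
}

.assertFraction <- function(x, field, lo = 0, hi = 1,
                            loOpen = TRUE, hiOpen = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (loOpen) x > lo else x >= lo) && (if (hiOpen) x < hi else x <= hi)
  if (!ok) stop(sprintf("invalid '%s': must lie in %s%g, %g%s", field,
                        if (loOpen) "(" else "[", lo, hi,
                        if (hiOpen) ")" else "]"), call. = FALSE)
  invisible(x)
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# expression matrix out of a SummarizedExperiment or plain matrix
.exprsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) return(SummarizedExperiment::assay(x))
  if (is.matrix(x)) return(x)
  stop("expected a SummarizedExperiment or a matrix")
}

.classesOf <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"class" %in% names(cd)) stop("colData must contain a 'class' column")
  cls <- as.character(cd$class)
  if (!all(cls %in% c("case", "control")))
    stop("sample class must be 'case' or 'control'")
  setNames(cls, colnames(x))
}

.batchesOf <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"batch" %in% names(cd)) stop("colData must contain a 'batch' column")
  setNames(as.character(cd$batch), colnames(x))
}
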