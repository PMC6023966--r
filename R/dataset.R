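#' Construct a binarized miRNA expression dataset
#'
#' A binarized dataset is a samples-by-miRNA 0/1 matrix together with sample
#' identifiers and binary annotations (1 = positive/diseased, 0 =
#' negative/healthy).  High expression is coded 1, low expression 0.
#'
#' @param x integer or numeric matrix of 0/1 values; columns are miRNAs and
#'   must be named, rows are samples.
#' @param annots vector of 0/1 sample annotations, one per row of `x`.
#' @param sample_ids optional vector of unique sample identifiers; defaults to
#'   the row names of `x` or `1:nrow(x)`.
#' @return An object of class `c("binarized_dataset", "mirna_dataset")` with
#'   fields `sample_ids`, `annots`, `mirna_ids` and `x` (integer matrix).
#' @seealso [read_dataset()], [continuous_dataset()], [check_consistency()]
#' @export
binarized_dataset <- function(x, annots, sample_ids = NULL) {
  ds <- new_dataset(x, annots, sample_ids, binary = TRUE)
  class(ds) <- c("binarized_dataset", "mirna_dataset")
  ds
}

#' Construct a continuous miRNA expression dataset
#'
#' Same layout as [binarized_dataset()] but with non-negative real-valued
#' expression entries, used for continuous circuit-output scoring.
#'
#' @inheritParams binarized_dataset
#' @param threshold optional binarization threshold in expression units
#'   (values at or above the threshold binarize to 1).
#' @return An object of class `c("continuous_dataset", "mirna_dataset")`.
#' @export
continuous_dataset <- function(x, annots, sample_ids = NULL, threshold = NULL) {
  ds <- new_dataset(x, annots, sample_ids, binary = FALSE)
  if (!is.null(threshold)) {
    stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
    ds$threshold <- as.numeric(threshold)
  }
  class(ds) <- c("continuous_dataset", "mirna_dataset")
  ds
}

new_dataset <- function(x, annots, sample_ids, binary) {
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    stop("empty dataset: at least one sample row is required", call. = FALSE)
  if (ncol(x) == 0L)
    stop("dataset has no miRNA columns: nothing to classify", call. = FALSE)
  mirna_ids <- colnames(x)
  if (is.null(mirna_ids) || anyNA(mirna_ids) || any(!nzchar(mirna_ids)))
    stop("all miRNA columns must be named", call. = FALSE)
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA ID: ",
         paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "),
         call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(x))
    stop("sample_ids length (", length(sample_ids), ") does not match row count (",
         nrow(x), ")", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(annots) != nrow(x))
    stop("annotation length (", length(annots), ") does not match row count (",
         nrow(x), ")", call. = FALSE)
  if (anyNA(annots) || !all(annots %in% c(0, 1)))
    stop("annotations must be 0 (negative/healthy) or 1 (positive/diseased)",
         call. = FALSE)
  if (anyNA(x))
    stop("missing values in the expression matrix are not supported", call. = FALSE)
  if (binary) {
    if (!all(x %in% c(0, 1))) {
      bad <- which(!(x %in% c(0, 1)))[1L]
      i <- (bad - 1L) %% nrow(x) + 1L
      j <- (bad - 1L) %/% nrow(x) + 1L
      stop("non-binary value ", x[i, j], " at sample '", sample_ids[i],
           "', miRNA '", mirna_ids[j], "'", call. = FALSE)
    }
    storage.mode(x) <- "integer"
  } else {
    if (!is.numeric(x) || any(!is.finite(x)))
      stop("continuous expression values must be finite numbers", call. = FALSE)
    if (any(x < 0))
      stop("continuous expression values must be non-negative", call. = FALSE)
    storage.mode(x) <- "double"
  }
  rownames(x) <- sample_ids
  list(sample_ids = sample_ids, annots = as.integer(annots),
       mirna_ids = mirna_ids, x = x)
}

#' Read a (binarized or continuous) expression table
#'
#' The on-disk dialect is a comma-separated UTF-8 table whose first two
#' columns are `ID` (unique sample identifier) and `Annots` (0/1 annotation),
#' followed by one column per miRNA.  Column tokens are arbitrary, so both the
#' generic `g1, g2, ...` naming and real miRNA names such as `miR-378` work.
#'
#' @param path path of the CSV file.
#' @param mode `"binary"` (0/1 entries, the default) or `"continuous"`
#'   (non-negative real entries).
#' @return A [binarized_dataset()] or [continuous_dataset()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("ID,Annots,g1,g2,g3", "1,0,1,1,0", "2,0,0,1,1", "3,1,1,0,0"), f)
#' ds <- read_dataset(f)
#' ds$mirna_ids
#' @export
read_dataset <- function(path, mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                         stringsAsFactors = FALSE)
  hdr <- names(tab)
  if (length(hdr) < 3L || hdr[1L] != "ID" || hdr[2L] != "Annots")
    stop("format error in '", path,
         "': header must start with columns ID, Annots followed by miRNA columns",
         call. = FALSE)
  if (anyDuplicated(hdr))
    stop("format error in '", path, "': duplicate header field: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    stop("empty dataset in '", path, "': header only, no sample rows",
         call. = FALSE)
  x <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(x))
    stop("format error in '", path, "': non-numeric expression entries",
         call. = FALSE)
  if (mode == "binary")
    binarized_dataset(x, tab$Annots, sample_ids = tab$ID)
  else
    continuous_dataset(x, tab$Annots, sample_ids = tab$ID)
}

#' Write a dataset back to the CSV dialect
#'
#' Round-trips bit-exactly through [read_dataset()]: cell values, miRNA column
#' order and sample order are preserved.
#'
#' @param ds a [binarized_dataset()] or [continuous_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mirna_dataset"))
  tab <- data.frame(ID = ds$sample_ids, Annots = ds$annots,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(ds$x, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write dataset to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Find contradictory duplicate profiles
#'
#' A perfect classifier can only exist when the data are consistent, i.e.
#' the same binarized profile has not been observed for both a positive and a
#' negative sample.  This reports every pair of samples that share a profile
#' but differ in annotation.
#'
#' @param ds a [binarized_dataset()].
#' @return A data frame with one row per conflicting pair: columns
#'   `sample_pos`, `sample_neg` (the clashing sample IDs) and `profile` (the
#'   shared 0/1 profile as a string).  Zero rows when the data are consistent.
#' @export
check_consistency <- function(ds) {
  stopifnot(inherits(ds, "binarized_dataset"))
  key <- apply(ds$x, 1L, paste, collapse = "")
  out <- list()
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    pos <- idx[ds$annots[idx] == 1L]
    neg <- idx[ds$annots[idx] == 0L]
    if (length(pos) && length(neg)) {
      grid <- expand.grid(p = pos, n = neg)
      out[[length(out) + 1L]] <- data.frame(
        sample_pos = ds$sample_ids[grid$p],
        sample_neg = ds$sample_ids[grid$n],
        profile = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_pos = character(), sample_neg = character(),
                      profile = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$sample_pos, res$sample_neg), , drop = FALSE]
}

#' Binarize a continuous dataset at a threshold
#'
#' Values at or above the threshold become 1 (High), values below become 0
#' (Low).  The choice of discretization method is deliberately left to the
#' user; this helper implements only the simple fixed-threshold rule.
#'
#' @param ds a [continuous_dataset()].
#' @param threshold binarization threshold in expression units; defaults to
#'   the threshold stored in the dataset, if any.
#' @return A [binarized_dataset()].
#' @export
binarize <- function(ds, threshold = NULL) {
  stopifnot(inherits(ds, "continuous_dataset"))
  if (is.null(threshold)) threshold <- ds$threshold
  if (is.null(threshold))
    stop("no binarization threshold given and none stored in the dataset",
         call. = FALSE)
  binarized_dataset((ds$x >= threshold) * 1L, ds$annots, ds$sample_ids)
}

#' @export
print.mirna_dataset <- function(x, ...) {
  kind <- if (inherits(x, "binarized_dataset")) "Binarized" else "Continuous"
  cat(kind, " miRNA dataset: ", length(x$sample_ids), " samples (",
      sum(x$annots == 1L), " positive, ", sum(x$annots == 0L), " negative), ",
      length(x$mirna_ids), " miRNAs\n", sep = "")
  if (!is.null(x$threshold))
    cat("Binarization threshold:", x$threshold, "\n")
  invisible(x)
}
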