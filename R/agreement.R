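# Pairwise Dice similarity across observers, long-form factor-tagged
# records, and mean +/- SD group summaries.

#' Dice similarity coefficient between two binary masks
#'
#' Computes `2|A intersect B| / (|A| + |B|)` over foreground pixel sets:
#' 1 for perfectly overlapping segmentations, 0 for disjoint ones. If
#' exactly one mask is empty the DSC is 0. If both masks are empty the
#' value is set by `empty_policy`: two observers who both report no tumour
#' can be scored as perfect agreement (`"agree"`, the default, returning 1),
#' as 0 (`"zero"`), or excluded from analysis (`"exclude"`, returning `NA`).
#' The result carries an `empty_pair` attribute flagging the convention case.
#'
#' @param a,b [mask_image] objects on the same pixel grid.
#' @param empty_policy both-empty convention: `"agree"`, `"zero"` or
#'   `"exclude"`.
#' @return DSC in \[0, 1\] (or `NA` under `"exclude"` for a both-empty
#'   pair), with attribute `empty_pair`.
#' @examples
#' px <- matrix(0, 4, 4); px[2:3, 2:3] <- 1
#' a <- mask_image(px, "i", "o1")
#' dsc(a, a)  # 1
#' @export
dsc <- function(a, b, empty_policy = c("agree", "zero", "exclude")) {
  empty_policy <- match.arg(empty_policy)
  stopifnot(inherits(a, "mask_image"), inherits(b, "mask_image"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop(sprintf("grid mismatch: %dx%d vs %dx%d",
                 nrow(a$pixels), ncol(a$pixels), nrow(b$pixels), ncol(b$pixels)))
  na <- sum(a$pixels)
  nb <- sum(b$pixels)
  if (na == 0 && nb == 0) {
    val <- switch(empty_policy, agree = 1, zero = 0, exclude = NA_real_)
    return(structure(val, empty_pair = TRUE))
  }
  inter <- sum(a$pixels & b$pixels)
  structure(2 * inter / (na + nb), empty_pair = FALSE)
}

#' Pairwise DSC matrix for one image
#'
#' Compares every observer against every other, yielding a symmetric
#' matrix with unit diagonal and `n(n-1)/2` unique pairwise values
#' (153 for 18 observers).
#'
#' @param masks list of >= 2 [mask_image]s for one image, common grid.
#' @param empty_policy see [dsc()].
#' @return An object of class `dsc_matrix`: `image_id`, `observers`,
#'   `values` (symmetric numeric matrix), `empty_pairs` (logical matrix)
#'   and `empty_policy`.
#' @export
pairwise_dsc_matrix <- function(masks, empty_policy = c("agree", "zero", "exclude")) {
  empty_policy <- match.arg(empty_policy)
  n <- length(masks)
  if (n < 2) stop("need at least 2 masks, got ", n)
  ids <- vapply(masks, function(m) m$observer_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate observer ids in mask list")
  image_id <- unique(vapply(masks, function(m) m$image_id, character(1)))
  if (length(image_id) != 1)
    stop("masks belong to different images: ", paste(image_id, collapse = ", "))
  vals <- diag(1, n)
  empt <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- dsc(masks[[i]], masks[[j]], empty_policy)
      vals[i, j] <- vals[j, i] <- as.numeric(d)
      empt[i, j] <- empt[j, i] <- attr(d, "empty_pair")
    }
  }
  dimnames(vals) <- dimnames(empt) <- list(ids, ids)
  structure(list(image_id = image_id, observers = ids, values = vals,
                 empty_pairs = empt, empty_policy = empty_policy),
            class = "dsc_matrix")
}

#' @export
print.dsc_matrix <- function(x, ...) {
  n <- length(x$observers)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<dsc_matrix> image %s: %d observers, %d pairs, mean DSC %.3f\n",
              x$image_id, n, n * (n - 1) / 2, mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Flatten DSC matrices into factor-tagged long-form records
#'
#' Each unordered observer pair of each image becomes one record tagged
#' with the image's tumour type and stage. With the canonical design
#' (9 images x 18 observers) this yields 1,377 records. Pairs excluded by
#' the `"exclude"` both-empty policy (DSC `NA`) are dropped.
#'
#' @param matrices list of [pairwise_dsc_matrix] results, one per design image.
#' @param design a [study_design] covering every matrix's `image_id`.
#' @return data.frame with columns `image_id`, `tumour_type`, `stage`,
#'   `observer_a`, `observer_b`, `dsc`, `empty_pair`.
#' @export
flatten_records <- function(matrices, design) {
  stopifnot(inherits(design, "study_design"))
  out <- lapply(matrices, function(m) {
    stopifnot(inherits(m, "dsc_matrix"))
    row <- match(m$image_id, design$images$image_id)
    if (is.na(row)) stop("matrix for unknown image_id: ", m$image_id)
    n <- length(m$observers)
    ut <- which(upper.tri(m$values), arr.ind = TRUE)
    data.frame(
      image_id = m$image_id,
      tumour_type = design$images$tumour_type[row],
      stage = design$images$stage[row],
      observer_a = m$observers[ut[, 1]],
      observer_b = m$observers[ut[, 2]],
      dsc = m$values[ut],
      empty_pair = m$empty_pairs[ut],
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec[!is.na(rec$dsc), , drop = FALSE]
}

#' Mean +/- SD agreement summary by a design factor
#'
#' Summarises DSC records per level of `tumour_type`, `stage`, their
#' crossing, or the high/low experience pairing. SD is the sample standard
#' deviation (n - 1 denominator). For `experience_pairing`, records are
#' restricted to pairs whose two observers sit in the same experience band:
#' both high (>50 cases) or both low (<10 cases); mixed and middle-band
#' pairs are excluded.
#'
#' @param records long-form records from [flatten_records()].
#' @param factor one of `"tumour_type"`, `"stage"`,
#'   `"tumour_type_x_stage"`, `"experience_pairing"`.
#' @param design a [study_design]; required for `experience_pairing`.
#' @return data.frame with columns `level`, `mean_dsc`, `sd_dsc`, `n`.
#'   Stage and tumour-type levels are ordered canonically.
#' @export
group_summary <- function(records,
                          factor = c("tumour_type", "stage",
                                     "tumour_type_x_stage", "experience_pairing"),
                          design = NULL) {
  factor <- match.arg(factor)
  if (!nrow(records)) stop("no records to summarise")
  if (factor == "experience_pairing") {
    if (is.null(design)) stop("experience_pairing needs the study design")
    flag <- experience_flag(design)
    fa <- flag[records$observer_a]
    fb <- flag[records$observer_b]
    keep <- !is.na(fa) & !is.na(fb) & fa == fb
    records <- records[keep, , drop = FALSE]
    lev <- fa[keep]
    levels_order <- c("high", "low")
  } else if (factor == "tumour_type_x_stage") {
    lev <- paste(records$tumour_type, records$stage, sep = ":")
    levels_order <- as.vector(outer(TUMOUR_TYPES, STAGES, paste, sep = ":"))
  } else {
    lev <- records[[factor]]
    levels_order <- if (factor == "stage") STAGES else TUMOUR_TYPES
  }
  levels_order <- levels_order[levels_order %in% lev]
  out <- do.call(rbind, lapply(levels_order, function(l) {
    v <- records$dsc[lev == l]
    data.frame(level = l,
               mean_dsc = if (length(v)) mean(v) else NA_real_,
               sd_dsc = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "factor") <- factor
  out
}

#' Export DSC records or a matrix as CSV
#'
#' `write_records_csv` writes the long form with 6-decimal DSC formatting
#' (byte-stable across reruns); `write_matrix_csv` writes one per-image
#' symmetric matrix with observer ids as header row/column.
#'
#' @param records data.frame from [flatten_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  out$dsc <- sprintf("%.6f", out$dsc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @param matrix_obj a `dsc_matrix`.
#' @export
write_matrix_csv <- function(matrix_obj, path) {
  stopifnot(inherits(matrix_obj, "dsc_matrix"))
  m <- matrix_obj$values
  out <- data.frame(observer = rownames(m),
                    apply(m, 2, function(col) sprintf("%.6f", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("observer", colnames(m))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
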