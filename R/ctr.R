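#' Remove stray blobs from a label mask
#'
#' Keeps the two largest 4-connected lung components and the single largest
#' heart component; every other foreground pixel becomes background. If only
#' one lung component exists it is kept alone. This guards the CTR geometry
#' against the stray-blob failure mode of imperfect segmentations.
#' Idempotent. Ties in component area are broken by first-encountered label
#' (deterministic).
#'
#' @param mask integer label mask (0 background, 1 lung, 2 heart).
#' @return cleaned mask with attribute `"cleanup_applied"` (`TRUE` if any
#'   pixel changed).
#' @export
clean_mask <- function(mask) {
  mask <- as_label_mask(mask)
  out <- mask
  for (spec in list(list(code = 1L, keep = 2L), list(code = 2L, keep = 1L))) {
    bin <- mask == spec$code
    if (!any(bin)) {
      stop_ctrseg(sprintf("missing structure: no %s pixels in mask",
                          names(CLASS_LEVELS)[CLASS_LEVELS == spec$code]),
                  "ctrseg_missing_structure")
    }
    lab <- EBImage::bwlabel(bin)  # 4-connected components
    sizes <- tabulate(lab[lab > 0])
    keep <- head(order(sizes, decreasing = TRUE), spec$keep)
    drop <- bin & !(lab %in% keep)
    out[drop] <- 0L
  }
  attr(out, "cleanup_applied") <- !identical(as.vector(out), as.vector(mask))
  out
}

#' Horizontal extent of a class set
#'
#' Columns are 1-based; the width is the inclusive pixel count
#' `right - left + 1`.
#'
#' @param mask integer label mask.
#' @param class_set class codes (0/1/2) or names
#'   (`"background"`, `"lung"`, `"heart"`).
#' @return named numeric vector `(left_col, right_col, width_px)`.
#' @export
horizontal_extent <- function(mask, class_set) {
  codes <- class_codes(class_set)
  hit <- which(colSums(matrix(mask %in% codes, nrow(mask))) > 0)
  if (length(hit) == 0) {
    stop_ctrseg(sprintf("missing structure: no pixels of class {%s}",
                        paste(class_set, collapse = ",")),
                "ctrseg_missing_structure")
  }
  c(left_col = min(hit), right_col = max(hit),
    width_px = max(hit) - min(hit) + 1)
}

#' Cardiothoracic ratio from a label mask
#'
#' The cardiac span is the maximal transverse extent of heart-class pixels;
#' the thoracic span is the maximal transverse extent over all lung-class
#' pixels (outer edge of the left lung to outer edge of the right lung). The
#' CTR is their quotient. Both widths are inclusive pixel counts; the
#' computation is exact and deterministic. By default stray components are
#' removed first with [clean_mask()].
#'
#' @param mask integer label mask (0 background, 1 lung, 2 heart).
#' @param do_cleanup run [clean_mask()] first (default `TRUE`).
#' @return an object of class `ctr_result`: cardiac/thoracic widths (px),
#'   `ctr`, the extremal columns of both spans, and whether cleanup changed
#'   the mask. A mask with no heart or no lung pixels raises a
#'   "missing structure" error — the signal that the image needs human
#'   review.
#' @export
#' @examples
#' m <- matrix(0L, 50, 100)
#' m[20:40, 10:90] <- 1L
#' m[25:38, 40:60] <- 2L
#' compute_ctr(m)$ctr  # 21 / 81
compute_ctr <- function(mask, do_cleanup = TRUE) {
  mask <- as_label_mask(mask)
  cleaned <- FALSE
  if (isTRUE(do_cleanup)) {
    mask <- clean_mask(mask)
    cleaned <- isTRUE(attr(mask, "cleanup_applied"))
  }
  heart <- horizontal_extent(mask, "heart")
  thorax <- horizontal_extent(mask, "lung")
  structure(list(
    cardiac_width_px = unname(heart["width_px"]),
    thoracic_width_px = unname(thorax["width_px"]),
    ctr = unname(heart["width_px"] / thorax["width_px"]),
    heart_cols = unname(heart[c("left_col", "right_col")]),
    thorax_cols = unname(thorax[c("left_col", "right_col")]),
    cleanup_applied = cleaned
  ), class = "ctr_result")
}

#' @export
print.ctr_result <- function(x, ...) {
  cat(sprintf("<ctr_result> CTR %.4f = cardiac %d px / thoracic %d px (heart cols %d..%d, thorax cols %d..%d)%s\n",
              x$ctr, x$cardiac_width_px, x$thoracic_width_px,
              x$heart_cols[1], x$heart_cols[2], x$thorax_cols[1], x$thorax_cols[2],
              if (x$cleanup_applied) ", cleanup applied" else ""))
  invisible(x)
}

#' @export
#' @rdname compute_ctr
#' @param x a `ctr_result`.
#' @param ... unused.
tidy.ctr_result <- function(x, ...) {
  tibble::tibble(cardiac_width_px = x$cardiac_width_px,
                 thoracic_width_px = x$thoracic_width_px,
                 ctr = x$ctr,
                 heart_left_col = x$heart_cols[1], heart_right_col = x$heart_cols[2],
                 thorax_left_col = x$thorax_cols[1], thorax_right_col = x$thorax_cols[2],
                 cleanup_applied = x$cleanup_applied)
}

#' Cardiomegaly call from a CTR value
#'
#' Cardiomegaly is called for a CTR strictly greater than the threshold
#' (default 50%); a CTR exactly at the threshold is classified negative.
#'
#' @param ctr CTR value(s), vectorised.
#' @param threshold decision threshold (default 0.50).
#' @return logical vector.
#' @export
classify_cardiomegaly <- function(ctr, threshold = 0.50) {
  if (any(!is.finite(ctr)) || any(ctr <= 0)) {
    stop_ctrseg("ctr values must be positive and finite", "ctrseg_parameter_error")
  }
  ctr > threshold
}

#' CTR table for a set of masks
#'
#' Applies [compute_ctr()] to each mask and collects one row per image.
#' Masks whose CTR extraction raises a "missing structure" error are kept in
#' the table with an `error_note` and `NA` values (the human-review signal)
#' rather than aborting the run.
#'
#' @param mask_paths character vector of mask PNG paths, or a list of mask
#'   matrices.
#' @param image_paths optional identifiers for the output rows.
#' @param do_cleanup forwarded to [compute_ctr()].
#' @param threshold cardiomegaly threshold.
#' @return a tibble with columns `image_path, cardiac_width_px,
#'   thoracic_width_px, ctr, cardiomegaly_flag, cleanup_applied, error_note`.
#' @export
ctr_table <- function(mask_paths, image_paths = NULL, do_cleanup = TRUE,
                      threshold = 0.50) {
  n <- length(mask_paths)
  ids <- image_paths %||%
    (if (is.character(mask_paths)) mask_paths else sprintf("mask_%03d", seq_len(n)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- if (is.character(mask_paths)) read_mask(mask_paths[[i]]) else mask_paths[[i]]
    res <- tryCatch(compute_ctr(mask, do_cleanup = do_cleanup),
                    ctrseg_missing_structure = function(e) e)
    if (inherits(res, "ctr_result")) {
      rows[[i]] <- tibble::tibble(
        image_path = ids[[i]],
        cardiac_width_px = res$cardiac_width_px,
        thoracic_width_px = res$thoracic_width_px,
        ctr = res$ctr,
        cardiomegaly_flag = classify_cardiomegaly(res$ctr, threshold),
        cleanup_applied = res$cleanup_applied,
        error_note = NA_character_)
    } else {
      rows[[i]] <- tibble::tibble(
        image_path = ids[[i]], cardiac_width_px = NA_real_,
        thoracic_width_px = NA_real_, ctr = NA_real_,
        cardiomegaly_flag = NA, cleanup_applied = NA,
        error_note = conditionMessage(res))
    }
  }
  dplyr::bind_rows(rows)
}
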