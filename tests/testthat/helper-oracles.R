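# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / first-principles formulas, never the package internals.

# random label mask with at least one lung and one heart pixel
random_mask <- function(h, w, p_bg = 0.5) {
  m <- matrix(sample(0:2, h * w, replace = TRUE,
                     prob = c(p_bg, (1 - p_bg) / 2, (1 - p_bg) / 2)), h, w)
  m[sample(h * w, 1)] <- 1L
  m[sample(h * w, 1)] <- 2L
  storage.mode(m) <- "integer"
  m
}

# per-pixel one-vs-rest confusion counting, explicit double loop
oracle_confusion <- function(pred, ref) {
  out <- list()
  for (cls in 0:2) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(ncol(pred))) {
        p <- pred[i, j] == cls
        r <- ref[i, j] == cls
        if (p && r) tp <- tp + 1
        else if (p && !r) fp <- fp + 1
        else if (!p && r) fn <- fn + 1
        else tn <- tn + 1
      }
    }
    out[[cls + 1]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  out
}

# column-scan CTR oracle: scan every column for presence of each class
oracle_ctr <- function(mask) {
  heart_cols <- integer(0)
  lung_cols <- integer(0)
  for (j in seq_len(ncol(mask))) {
    col <- mask[, j]
    if (any(col == 2L)) heart_cols <- c(heart_cols, j)
    if (any(col == 1L)) lung_cols <- c(lung_cols, j)
  }
  cw <- max(heart_cols) - min(heart_cols) + 1
  tw <- max(lung_cols) - min(lung_cols) + 1
  list(cardiac = cw, thoracic = tw, ctr = cw / tw)
}

# 4-connected component labeling by queue-based flood fill
oracle_label4 <- function(bin) {
  lab <- matrix(0L, nrow(bin), ncol(bin))
  cur <- 0L
  for (j in seq_len(ncol(bin))) for (i in seq_len(nrow(bin))) {
    if (bin[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- q[1] + d[1]; jj <- q[2] + d[2]
          if (ii >= 1 && ii <= nrow(bin) && jj >= 1 && jj <= ncol(bin) &&
              bin[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue <- c(queue, list(c(ii, jj)))
          }
        }
      }
    }
  }
  lab
}

# keep the k largest components of class `cls` (ties: smaller label first)
oracle_keep_largest <- function(mask, cls, k) {
  lab <- oracle_label4(mask == cls)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]
  out <- mask
  out[mask == cls & !(lab %in% keep)] <- 0L
  out
}

# AUC by exhaustive pairwise counting with the half-credit tie rule
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

tiny_phantom_params <- function(...) {
  phantom_params(width_px = 64L, height_px = 64L, ...)
}

# Minimal 16-bit grayscale PNG writer (stored-deflate blocks) so the 16-bit
# read path can be tested without any external tool. `values` is an integer
# matrix in 0..65535.
write_png16_gray <- function(values, path) {
  crc_table <- local({
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
      }
      tab[n + 1] <- c
    }
    tab
  })
  crc32 <- function(bytes) {
    c <- -1L
    for (b in as.integer(bytes)) {
      c <- bitwXor(crc_table[bitwAnd(bitwXor(c, b), 255L) + 1L], bitwShiftR(c, 8))
    }
    bitwXor(c, -1L)
  }
  u32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(as.numeric(crc32(body)) %% 2^32))
  }
  h <- nrow(values); w <- ncol(values)
  ihdr <- c(u32(w), u32(h), as.raw(c(16, 0, 0, 0, 0)))
  # raw scanlines: filter byte 0 + big-endian 16-bit samples
  scan <- unlist(lapply(seq_len(h), function(i) {
    v <- as.integer(values[i, ])
    c(as.raw(0), as.raw(rbind(v %/% 256L, v %% 256L)))
  }))
  # zlib stream with a single stored deflate block
  stopifnot(length(scan) <= 65535)
  len <- length(scan)
  adler <- local({
    a <- 1; b <- 0
    for (x in as.integer(scan)) { a <- (a + x) %% 65521; b <- (b + a) %% 65521 }
    b * 65536 + a
  })
  idat <- c(as.raw(c(0x78, 0x01, 0x01)),
            as.raw(c(len %% 256, len %/% 256,
                     255 - len %% 256, 255 - len %/% 256)),
            scan, u32(adler))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat),
           chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
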