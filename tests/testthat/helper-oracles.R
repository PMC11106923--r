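# Independent slow oracles used to cross-check the implementation.

# Connected-component labelling by explicit stack-based flood fill.
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% h) + 1L
      c <- ((cur - 1L) %/% h) + 1L
      for (j in seq_len(nrow(nb))) {
        rr <- r + nb[j, 1]; cc <- c + nb[j, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack <- c(stack, (cc - 1L) * h + rr)
        }
      }
    }
  }
  lab
}

# Naive per-pixel loop recomputation of Dice and IoU.
brute_overlap <- function(pred, truth) {
  tp <- 0L; np <- 0L; nt <- 0L; un <- 0L
  for (i in seq_along(pred)) {
    if (pred[i]) np <- np + 1L
    if (truth[i]) nt <- nt + 1L
    if (pred[i] && truth[i]) tp <- tp + 1L
    if (pred[i] || truth[i]) un <- un + 1L
  }
  list(dice = if (np + nt > 0) 2 * tp / (np + nt) else NA_real_,
       iou = if (un > 0) tp / un else NA_real_)
}

# Small phantom used by unit tests (fast; acceptance tests use 512^2).
small_phantom <- function(cax = 30, ctr = 0.30, seed = 5, size = 192, jitter = 0) {
  generate_phantom(phantom_spec(image_size = c(size, size), true_cax_deg = cax,
                                true_ctr = ctr, boundary_jitter_px = jitter,
                                seed = seed))
}

# Random blob mask from seeded rectangles.
random_mask <- function(h, w, n_blobs = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(n_blobs)) {
      r <- sort(sample(h, 2)); c <- sort(sample(w, 2))
      m[r[1]:r[2], c[1]:c[2]] <- TRUE
    }
    m
  })
}
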