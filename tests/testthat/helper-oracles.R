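# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-pixel loops, direct formulas) so they cannot
# share a defect with the implementation they check.

random_mask <- function(h, w, p = 0.3, image_id = "img", observer_id = "obs") {
  mask_image(matrix(stats::rbinom(h * w, 1, p), h, w), image_id, observer_id)
}

square_mask <- function(h, w, r1, r2, c1, c2, image_id = "img", observer_id = "obs") {
  px <- matrix(0L, h, w)
  px[r1:r2, c1:c2] <- 1L
  mask_image(px, image_id, observer_id)
}

# per-pixel loop Dice: counts |A|, |B|, |A n B| one pixel at a time
dsc_oracle <- function(a, b, both_empty = 1) {
  na <- 0; nb <- 0; ni <- 0
  for (i in seq_len(nrow(a$pixels))) {
    for (j in seq_len(ncol(a$pixels))) {
      pa <- a$pixels[i, j]; pb <- b$pixels[i, j]
      na <- na + pa; nb <- nb + pb
      if (pa == 1 && pb == 1) ni <- ni + 1
    }
  }
  if (na + nb == 0) return(both_empty)
  2 * ni / (na + nb)
}

# per-pixel recount of the aggregate agreement map
aggregate_oracle <- function(masks) {
  h <- nrow(masks[[1]]$pixels); w <- ncol(masks[[1]]$pixels)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    k <- 0L
    for (m in masks) if (m$pixels[i, j] == 1L) k <- k + 1L
    out[i, j] <- k
  }
  out
}

# Dunn z statistics recomputed from first principles: mean ranks via
# sort-order averaging, tie term via run-length counts on sorted values
dunn_oracle <- function(values, groups) {
  n <- length(values)
  sorted <- sort(values)
  runs <- rle(sorted)
  ranks <- numeric(n)
  pos <- 1
  start_rank <- 1
  rank_of_value <- list()
  for (k in seq_along(runs$values)) {
    len <- runs$lengths[k]
    rank_of_value[[as.character(runs$values[k])]] <-
      mean(seq(start_rank, start_rank + len - 1))
    start_rank <- start_rank + len
  }
  for (i in seq_len(n)) ranks[i] <- rank_of_value[[as.character(values[i])]]
  tie_term <- sum(runs$lengths^3 - runs$lengths)
  V <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  levs <- sort(unique(groups))
  out <- NULL
  for (i in seq_len(length(levs) - 1)) {
    for (j in seq(i + 1, length(levs))) {
      ri <- mean(ranks[groups == levs[i]])
      rj <- mean(ranks[groups == levs[j]])
      ni <- sum(groups == levs[i]); nj <- sum(groups == levs[j])
      z <- (ri - rj) / sqrt(V * (1 / ni + 1 / nj))
      out <- rbind(out, data.frame(group_a = levs[i], group_b = levs[j], z = z))
    }
  }
  out
}

# all permutations via a different construction than the package's
# (index-set recursion rather than insertion)
perms_oracle <- function(n) {
  gen <- function(idx) {
    if (length(idx) == 1) return(list(idx))
    out <- list()
    for (k in seq_along(idx))
      for (rest in gen(idx[-k]))
        out[[length(out) + 1]] <- c(idx[k], rest)
    out
  }
  gen(seq_len(n))
}

make_zero_scenario <- function(n_images = 3, n_observers = 6, grid = c(64, 64),
                               master_seed = 11) {
  images <- data.frame(
    image_id = paste0("z", seq_len(n_images)),
    tumour_type = TUMOUR_TYPES_local()[seq_len(n_images)],
    stage = STAGES_local()[seq_len(n_images)])
  models <- replicate(n_images,
                      rater_model(boundary_jitter = 0, omission_prob = 0,
                                  spurious_prob = 0),
                      simplify = FALSE)
  scenario_spec(images, models, n_observers = n_observers,
                master_seed = master_seed, grid = grid)
}

TUMOUR_TYPES_local <- function() c("metastasis", "HGG", "LGG")
STAGES_local <- function() c("before", "during", "completion")

# 4-connected component count by iterative flood fill
flood_count <- function(px) {
  seen <- matrix(FALSE, nrow(px), ncol(px))
  comp <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] == 1 && !seen[i, j]) {
      comp <- comp + 1
      stack <- list(c(i, j))
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        r <- cur[1]; c <- cur[2]
        if (r < 1 || c < 1 || r > nrow(px) || c > ncol(px)) next
        if (seen[r, c] || px[r, c] == 0) next
        seen[r, c] <- TRUE
        stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
      }
    }
  }
  comp
}
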