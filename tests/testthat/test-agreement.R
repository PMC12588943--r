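test_that("dsc matches the direct formula on simple configurations", {
  a <- square_mask(10, 10, 2, 3, 2, 2, observer_id = "a")  # |A| = 2
  b <- square_mask(10, 10, 3, 4, 2, 2, observer_id = "b")  # |B| = 2, overlap 1
  expect_equal(as.numeric(dsc(a, b)), 0.5)
  expect_equal(as.numeric(dsc(a, a)), 1)
  disjoint <- square_mask(10, 10, 7, 8, 7, 8, observer_id = "c")
  expect_equal(as.numeric(dsc(a, disjoint)), 0)
})

test_that("both-empty pairs follow the configured policy and are flagged", {
  e1 <- mask_image(matrix(0, 5, 5), "i", "a")
  e2 <- mask_image(matrix(0, 5, 5), "i", "b")
  full <- mask_image(matrix(1, 5, 5), "i", "c")
  expect_equal(as.numeric(dsc(e1, e2, "agree")), 1)
  expect_equal(as.numeric(dsc(e1, e2, "zero")), 0)
  expect_true(is.na(dsc(e1, e2, "exclude")))
  expect_true(attr(dsc(e1, e2, "agree"), "empty_pair"))
  # one empty, one not: always 0, not a convention case
  expect_equal(as.numeric(dsc(e1, full)), 0)
  expect_false(attr(dsc(e1, full), "empty_pair"))
})

test_that("dsc is symmetric and matches the per-pixel oracle on random masks", {
  set.seed(101)
  for (i in 1:60) {
    h <- sample(3:32, 1); w <- sample(3:32, 1)
    a <- random_mask(h, w, runif(1, 0, 0.6), observer_id = "a")
    b <- random_mask(h, w, runif(1, 0, 0.6), observer_id = "b")
    expect_equal(as.numeric(dsc(a, b)), as.numeric(dsc(b, a)))
    expect_equal(as.numeric(dsc(a, b)), dsc_oracle(a, b))
  }
})

test_that("removing overlap pixels never increases dsc", {
  set.seed(5)
  a <- random_mask(16, 16, 0.5, observer_id = "a")
  b <- a
  prev <- as.numeric(dsc(a, b))
  overlap <- which(a$pixels == 1 & b$pixels == 1)
  for (k in overlap[seq_len(min(20, length(overlap)))]) {
    px <- b$pixels; px[k] <- 0L
    b <- mask_image(px, "img", "b")
    cur <- as.numeric(dsc(a, b))
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("dsc errors on mismatched grids", {
  a <- random_mask(5, 5); b <- random_mask(5, 6, observer_id = "b")
  expect_error(dsc(a, b), "grid mismatch")
})

test_that("pairwise matrix is symmetric with unit diagonal and C(n,2) pairs", {
  set.seed(11)
  masks <- lapply(1:7, function(i) random_mask(12, 12, 0.4,
                                               observer_id = paste0("o", i)))
  M <- pairwise_dsc_matrix(masks)
  expect_identical(M$values, t(M$values))
  expect_equal(diag(M$values), setNames(rep(1, 7), M$observers))
  expect_equal(sum(upper.tri(M$values)), 21)
  expect_true(all(M$values >= 0 & M$values <= 1))

  expect_error(pairwise_dsc_matrix(masks[1]), "at least 2")
  copies <- lapply(1:4, function(i) mask_image(masks[[1]]$pixels, "img",
                                               paste0("c", i)))
  Mc <- pairwise_dsc_matrix(copies)
  expect_true(all(Mc$values == 1))
})

test_that("records flatten with factor tags and conserve pair counts", {
  ds <- simulate_study(make_zero_scenario(n_images = 3, n_observers = 5,
                                          grid = c(48, 48)))
  mats <- lapply(ds$design$images$image_id,
                 function(i) pairwise_dsc_matrix(image_masks(ds, i)))
  rec <- flatten_records(mats, ds$design)
  expect_equal(nrow(rec), 3 * choose(5, 2))
  expect_true(all(rec$observer_a != rec$observer_b))
  key <- paste(rec$image_id, pmin(rec$observer_a, rec$observer_b),
               pmax(rec$observer_a, rec$observer_b))
  expect_false(anyDuplicated(key) > 0)
  expect_identical(sort(unique(rec$stage)), sort(ds$design$images$stage))

  bad <- mats[[1]]; bad$image_id <- "nope"
  expect_error(flatten_records(list(bad), ds$design), "unknown image_id")
})

test_that("group summaries report sample mean/SD and conserve n across levels", {
  rec <- data.frame(image_id = "a", tumour_type = "HGG", stage = "before",
                    observer_a = "x", observer_b = "y",
                    dsc = rep(0.5, 4), empty_pair = FALSE)
  s <- group_summary(rec, "stage")
  expect_equal(s$mean_dsc, 0.5)
  expect_equal(s$sd_dsc, 0)

  rec2 <- data.frame(image_id = c("a", "a", "b", "b"),
                     tumour_type = c("HGG", "HGG", "LGG", "LGG"),
                     stage = "before",
                     observer_a = "x", observer_b = "y",
                     dsc = c(0, 1, 1, 1), empty_pair = FALSE)
  s2 <- group_summary(rec2, "tumour_type")
  expect_equal(s2$mean_dsc[s2$level == "HGG"], 0.5)
  expect_equal(s2$mean_dsc[s2$level == "LGG"], 1.0)
  # sample SD, n-1 denominator
  expect_equal(s2$sd_dsc[s2$level == "HGG"], sd(c(0, 1)))
  expect_equal(sum(s2$n), nrow(rec2))
})

test_that("experience pairing keeps only within-band pairs", {
  obs <- data.frame(observer_id = c("h1", "h2", "l1", "l2", "m1"),
                    grade = "fellow",
                    experience_band = c(">50", ">50", "<10", "<10", "10-25"))
  imgs <- data.frame(image_id = "a", tumour_type = "HGG", stage = "before")
  design <- study_design(imgs, obs)
  pairs <- t(combn(obs$observer_id, 2))
  rec <- data.frame(image_id = "a", tumour_type = "HGG", stage = "before",
                    observer_a = pairs[, 1], observer_b = pairs[, 2],
                    dsc = seq(0.1, 1, length.out = nrow(pairs)),
                    empty_pair = FALSE)
  s <- group_summary(rec, "experience_pairing", design)
  # only (h1,h2) and (l1,l2) survive: one pair per band
  expect_equal(s$n, c(1, 1))
  expect_identical(s$level, c("high", "low"))
  expect_equal(s$mean_dsc[1], rec$dsc[rec$observer_a == "h1" & rec$observer_b == "h2"])
})

test_that("exclude policy drops both-empty pairs from the records", {
  e <- matrix(0, 6, 6)
  f <- matrix(0, 6, 6); f[2:3, 2:3] <- 1
  masks <- list(mask_image(e, "a", "o1"), mask_image(e, "a", "o2"),
                mask_image(f, "a", "o3"))
  M <- pairwise_dsc_matrix(masks, empty_policy = "exclude")
  design <- study_design(
    data.frame(image_id = "a", tumour_type = "HGG", stage = "completion"),
    data.frame(observer_id = c("o1", "o2", "o3"), grade = "fellow",
               experience_band = "10-25"))
  rec <- flatten_records(list(M), design)
  expect_equal(nrow(rec), 2)  # the (o1,o2) both-empty pair is excluded
  expect_true(all(rec$dsc == 0))
})
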