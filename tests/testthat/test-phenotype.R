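man <- item_manifest()

test_that("scale totals respect floors, flips and clinical flags", {
  # all-minimum responses hit each instrument's floor
  lo <- matrix(rep(man$level_min, each = 2), nrow = 2, byrow = FALSE,
               dimnames = list(NULL, man$item_id))
  # a reverse-scored item at its minimum contributes its maximum after flip
  s <- score_scales(lo, man)
  floors <- sapply(unique(man$scale), function(sc) {
    sel <- man$scale == sc
    sum(ifelse(man$reverse_scored[sel],
               man$level_min[sel] + man$n_levels[sel] - 1, man$level_min[sel]))
  })
  for (sc in unique(man$scale)) expect_equal(s[[sc]][1], floors[[sc]])
})

test_that("clinical threshold comparators are as printed", {
  mk <- function(ocir_total, stai_total) {
    # raw minima everywhere; reversed items at raw maximum so that their
    # flipped contribution is the instrument minimum
    lmax <- man$level_min + man$n_levels - 1
    resp <- matrix(ifelse(man$reverse_scored, lmax, man$level_min),
                   nrow = 1, dimnames = list(NULL, man$item_id))
    fill <- function(resp, scale, total) {
      floor_total <- sum(man$level_min[man$scale == scale])
      need <- total - floor_total
      for (j in which(man$scale == scale & !man$reverse_scored)) {
        add <- min(lmax[j] - resp[1, j], need)
        resp[1, j] <- resp[1, j] + add
        need <- need - add
        if (need <= 0) break
      }
      stopifnot(need <= 0)
      resp
    }
    resp <- fill(resp, "OCIR", ocir_total)
    resp <- fill(resp, "STAI", stai_total)
    score_scales(resp, man)
  }
  s <- mk(21, 41)
  expect_equal(s$OCIR, 21)
  expect_true(s$ocir_ge_21)        # >= 21 flags
  expect_equal(s$STAI, 41)
  expect_false(s$stai_gt_41)       # strict > does not flag at 41
  s2 <- mk(20, 42)
  expect_false(s2$ocir_ge_21)
  expect_true(s2$stai_gt_41)
})

test_that("missing responses are an error naming the item", {
  resp <- matrix(1, nrow = 2, ncol = 209, dimnames = list(NULL, man$item_id))
  resp[1, 5] <- NA
  expect_error(score_scales(resp, man), man$item_id[5], fixed = TRUE)
  expect_error(score_scales(resp[, 1:100], man), "209")
})

test_that("projection is a linear weighted sum with exact z-scoring", {
  w <- matrix(0, 209, 3, dimnames = list(man$item_id, c("AD", "CIT", "SW")))
  w[7, "AD"] <- 1   # indicator weight picks out one item
  class(w) <- c("dimension_weights", class(w))
  set.seed(2)
  resp <- matrix(sample(0:3, 6 * 209, TRUE), 6,
                 dimnames = list(NULL, man$item_id))
  proj <- project_dimensions(resp, w)
  expect_equal(proj$AD, as.numeric(resp[, 7]))
  expect_equal(proj$CIT, rep(0, 6))
  expect_equal(mean(proj$AD_z), 0, tolerance = 1e-9)
  expect_equal(sd(proj$AD_z), 1, tolerance = 1e-9)
  # zero responses project to zero
  expect_equal(project_dimensions(matrix(0, 3, 209), w, z = FALSE)$AD,
               rep(0, 3))
  # linearity before z-scoring
  wfull <- default_dimension_weights()
  a <- matrix(sample(0:3, 2 * 209, TRUE), 2)
  b <- matrix(sample(0:3, 2 * 209, TRUE), 2)
  lhs <- project_dimensions(2 * a + 3 * b, wfull, z = FALSE)
  rhs <- 2 * project_dimensions(a, wfull, z = FALSE)[, c("AD", "CIT", "SW")] +
    3 * project_dimensions(b, wfull, z = FALSE)[, c("AD", "CIT", "SW")]
  expect_equal(lhs[, c("AD", "CIT", "SW")], rhs, tolerance = 1e-12)
})

test_that("generator-matched weights recover the true factors", {
  m <- latent_model()
  sim <- simulate_items(m, 2000, seed = 51)
  proj <- project_dimensions(sim$responses, default_dimension_weights(m))
  for (d in c("AD", "CIT", "SW"))
    expect_gt(cor(proj[[d]], sim$truth[[d]]), 0.9)
  # inter-dimension raw-score correlations stay in the moderate band
  emp <- cor(as.matrix(proj[, c("AD", "CIT", "SW")]))
  tgt <- default_factor_corr()
  for (pair in list(c("AD", "CIT"), c("AD", "SW"), c("CIT", "SW")))
    expect_lt(abs(emp[pair[1], pair[2]] - tgt[pair[1], pair[2]]), 0.1)
})

test_that("weight matrices survive a CSV round trip and check alignment", {
  w <- default_dimension_weights()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dimension_weights(w, path)
  w2 <- read_dimension_weights(path, man)
  expect_equal(unclass(w2)[, ], unclass(w)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # misaligned items are rejected
  df <- utils::read.csv(path)
  df <- df[c(2, 1, 3:209), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_dimension_weights(path2, man), "order")
})
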