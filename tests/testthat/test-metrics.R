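# Region extraction, DSC, HD95, special-case scoring and aggregation.

test_that("region extraction follows the nested WT/TC/ET definitions", {
  lab <- matrix(0L, 6, 6)
  lab[1, 1:5] <- 1L                       # 5 px necrosis
  lab[2, 1:6] <- 2L; lab[3, 6] <- 2L      # 7 px edema
  lab[4, 1:3] <- 3L                       # 3 px enhancing
  r <- extract_regions(lab)
  expect_equal(sum(r$et), 3)
  expect_equal(sum(r$tc), 8)
  expect_equal(sum(r$wt), 15)
  expect_true(all(r$tc[r$et]))
  expect_true(all(r$wt[r$tc]))
  # all-background map gives three empty masks
  r0 <- extract_regions(matrix(0L, 4, 4))
  expect_false(any(r0$et) || any(r0$tc) || any(r0$wt))
  expect_error(extract_regions(matrix(4L, 2, 2)), "outside")
})

test_that("nesting holds for arbitrary label maps", {
  set.seed(31)
  for (rep in 1:20) {
    lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    r <- extract_regions(lab)
    expect_true(all(r$wt[r$tc]) && all(r$tc[r$et]))
  }
})

test_that("DSC handles identical, disjoint and counted-overlap masks", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, !a), 0)
  # TP=2, FP=1, FN=1 -> 4/6
  pred <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  gt <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(dsc(pred, gt), 2 / 3)
  expect_equal(dsc(pred, gt), dsc(gt, pred))
  expect_equal(dsc(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dsc(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("false positives never increase DSC for nested predictions", {
  gt <- matrix(FALSE, 8, 8); gt[3:5, 3:5] <- TRUE
  pred <- gt
  prev <- dsc(pred, gt)
  for (k in 1:4) {
    pred[1, k] <- TRUE                     # grow a false-positive region
    cur <- dsc(pred, gt)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("HD95 basic geometry: identity and a 3-4-5 offset", {
  m <- matrix(FALSE, 8, 8); m[2:4, 2:5] <- TRUE
  expect_equal(hd95(m, m), 0)
  a <- matrix(FALSE, 8, 8); a[1, 1] <- TRUE
  b <- matrix(FALSE, 8, 8); b[4, 5] <- TRUE
  expect_equal(hd95(a, b), 5)
})

test_that("HD95 agrees with the exhaustive all-pairs oracle on random masks", {
  set.seed(32)
  for (rep in 1:12) {
    a <- matrix(runif(16 * 16) < 0.2, 16, 16)
    b <- matrix(runif(16 * 16) < 0.2, 16, 16)
    if (!any(a) || !any(b)) next
    got <- hd95(a, b)
    expect_equal(got, hd95_oracle(a, b), tolerance = 1e-9)
    expect_equal(got, hd95(b, a))                       # symmetric by max
    # the 95th percentile never exceeds the full Hausdorff distance
    hd100 <- local({
      bd <- function(m) which(m & !(rbind(FALSE, m[-16, ]) & rbind(m[-1, ], FALSE) &
                                    cbind(FALSE, m[, -16]) & cbind(m[, -1], FALSE)),
                              arr.ind = TRUE)
      pa <- bd(a); ga <- bd(b)
      dmin <- function(u, v) apply(u, 1, function(p)
        min(sqrt((p[1] - v[, 1])^2 + (p[2] - v[, 2])^2)))
      max(max(dmin(pa, ga)), max(dmin(ga, pa)))
    })
    expect_lte(got, hd100 + 1e-12)
  }
})

test_that("HD95 on an empty mask is undefined with a reason, not zero", {
  m <- matrix(FALSE, 4, 4); n <- matrix(TRUE, 4, 4)
  h <- hd95(m, n)
  expect_true(is.na(h))
  expect_match(attr(h, "reason"), "empty")
})

test_that("score_case applies the enhancing-tumor special rule exactly", {
  gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 2L            # tumor, but no ET
  pred_fp <- gt; pred_fp[3, 3] <- 3L                     # false-positive ET
  r <- score_case(pred_fp, gt)
  expect_equal(r$dsc[r$region == "ET"], 0)
  expect_true(r$special[r$region == "ET"])
  pred_ok <- gt
  r2 <- score_case(pred_ok, gt)
  expect_equal(r2$dsc[r2$region == "ET"], 1)
  expect_true(r2$special[r2$region == "ET"])
  # regular path when ground-truth ET exists
  gt2 <- gt; gt2[4, 4] <- 3L
  r3 <- score_case(pred_fp, gt2)
  expect_false(r3$special[r3$region == "ET"])
  expect_false(any(r3$special[r3$region != "ET"]))
})

test_that("scoring a case against itself yields DSC 1 and HD95 0", {
  case <- generate_case(tiny_phantom_spec())
  r <- score_case(case$labels, case$labels)
  expect_equal(r$dsc, rep(1, 3))
  expect_equal(r$hd95, rep(0, 3))
})

test_that("aggregation removes special values like a brute-force filter", {
  set.seed(33)
  recs <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(case = paste0("c", i), region = c("ET", "TC", "WT"),
               dsc = runif(3), hd95 = c(runif(2, 0, 10), NA),
               special = c(i <= 3, FALSE, FALSE),
               hd95_reason = c("", "", "empty prediction"))
  }))
  s <- aggregate_records(recs)
  et <- recs[recs$region == "ET" & !recs$special, ]
  expect_equal(s$per_region$mean_dsc[s$per_region$region == "ET"], mean(et$dsc))
  expect_equal(s$per_region$n_dsc, c(7, 10, 10))
  expect_equal(s$per_region$n_hd95, c(10, 10, 0))
  expect_true(is.na(s$per_region$mean_hd95[3]))
  expect_equal(s$overall$mean_dsc, mean(s$per_region$mean_dsc))
})

test_that("a single record aggregates to itself", {
  r <- data.frame(case = "c", region = c("ET", "TC", "WT"),
                  dsc = c(0.5, 0.6, 0.7), hd95 = c(1, 2, 3),
                  special = FALSE, hd95_reason = "")
  s <- aggregate_records(r)
  expect_equal(s$per_region$mean_dsc, c(0.5, 0.6, 0.7))
  expect_equal(s$overall$mean_hd95, 2)
})

test_that("nesting holds on every generated phantom case", {
  ds <- generate_dataset(6, tiny_phantom_spec(seed = 9), empty_et_fraction = 1 / 3)
  for (cs in ds) {
    r <- extract_regions(cs$labels)
    expect_true(all(r$wt[r$tc]) && all(r$tc[r$et]))
  }
})
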