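test_that("ES matches the brute-force running sum on a tiny ranking", {
  set.seed(61)
  ranked <- stats::setNames(round(rnorm(10), 2), paste0("g", 1:10))
  set3 <- c("g2", "g5", "g9")
  res <- prerankedGSEA(ranked, list(s = set3), n_perm = 50, seed = 1)
  expect_equal(res["s", "ES"], es_brute(ranked, set3))
  ## weight p = 0 variant
  res0 <- prerankedGSEA(ranked, list(s = set3), n_perm = 50, p = 0,
                        seed = 1)
  expect_equal(res0["s", "ES"], es_brute(ranked, set3, p = 0))
})

test_that("extremal and interleaved sets behave as expected", {
  ranked <- stats::setNames(seq(5, -5, length.out = 40), paste0("g", 1:40))
  top <- paste0("g", 1:8)
  res <- prerankedGSEA(ranked, list(top = top), n_perm = 200, seed = 2)
  expect_gt(res["top", "ES"], 0)
  expect_lt(res["top", "p_value"], 0.05)
  ## top-k set attains the maximal ES among same-size sets
  set.seed(3)
  for (i in 1:20) {
    other <- sample(names(ranked), 8)
    expect_lte(es_brute(ranked, other), es_brute(ranked, top) + 1e-12)
  }
  ## uniformly interleaved set is not significant
  inter <- paste0("g", seq(3, 40, 5))
  res2 <- prerankedGSEA(ranked, list(i = inter), n_perm = 200, seed = 2)
  expect_gt(res2["i", "p_value"], 0.05)
})

test_that("ES is invariant to positive scaling of scores", {
  set.seed(62)
  ranked <- stats::setNames(rnorm(50), paste0("g", 1:50))
  set_ <- sample(names(ranked), 10)
  e1 <- prerankedGSEA(ranked, list(s = set_), n_perm = 10, seed = 1)
  e2 <- prerankedGSEA(ranked * 7, list(s = set_), n_perm = 10, seed = 1)
  expect_equal(e1["s", "ES"], e2["s", "ES"])
})

test_that("running sum returns to zero at the final position", {
  set.seed(63)
  ranked <- stats::setNames(rnorm(30), paste0("g", 1:30))
  hit <- names(ranked) %in% sample(names(ranked), 6)
  s <- sort(ranked, decreasing = TRUE)
  hit <- names(s) %in% names(ranked)[hit]
  w <- abs(s)
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  expect_equal(sum(inc), 0)
})

test_that("permutation p-values are uniform under null rankings", {
  set.seed(64)
  ranked <- stats::setNames(rnorm(300), paste0("g", 1:300))
  sets <- lapply(1:50, function(i) sample(names(ranked), 15))
  names(sets) <- paste0("s", 1:50)
  res <- prerankedGSEA(ranked, sets, n_perm = 200, seed = 5)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NES sign matches ES and agrees with fgsea on direction", {
  skip_if_not_installed("fgsea")
  set.seed(65)
  ranked <- stats::setNames(rnorm(200), paste0("g", 1:200))
  ranked[paste0("g", 1:15)] <- ranked[paste0("g", 1:15)] + 2
  sets <- list(up = paste0("g", 1:15), rnd = paste0("g", 100:120))
  res <- prerankedGSEA(ranked, sets, n_perm = 500, seed = 6)
  expect_true(all(sign(res$NES) == sign(res$ES)))
  expect_identical(res["up", "direction"], "up")
  fg <- suppressWarnings(fgsea::fgsea(sets, ranked, nperm = 500))
  expect_equal(sign(res[fg$pathway, "ES"]), sign(fg$ES))
  expect_lt(res["up", "p_value"], 0.05)
  expect_true(fg$pval[fg$pathway == "up"] < 0.05)
})

test_that("pathway change categories cover the four-way table", {
  rx <- data.frame(set = c("a", "b", "c", "d"),
                   direction = c("up", "up", "up", "down"),
                   p_value = c(0.01, 0.3, 0.01, 0.01))
  rxh <- data.frame(set = c("a", "b", "c", "d"),
                    direction = c("up", "up", "down", "down"),
                    p_value = c(0.3, 0.01, 0.02, 0.02))
  out <- pathwayChangeCategories(rx, rxh)
  expect_identical(out$category,
                   c("Rx_only", "RxH_only", "both_reverse_direction",
                     "both_same_direction"))
  expect_error(pathwayChangeCategories(rx, rxh[1:2, ]), "mismatch")
})

test_that("reference-set overlap fractions and enrichment behave", {
  calls <- data.frame(gene = paste0("g", 1:20),
                      is_cis = rep(c(TRUE, FALSE), 10),
                      logFC = c(seq(2, 0.5, length.out = 10),
                                seq(-0.5, -2, length.out = 10)))
  refs <- list(up_ref = paste0("g", 1:8), none = paste0("x", 1:6))
  expect_error(referenceSetOverlap(calls, list(empty = character())),
               "empty")
  res <- suppressWarnings(referenceSetOverlap(calls, refs, n_perm = 200,
                                              seed = 7))
  expect_equal(res$fractions["all", "none"], 0)
  expect_equal(res$fractions["all", "up_ref"], 8 / 20)
  ## a reference set covering every call has fraction 1
  res2 <- suppressWarnings(referenceSetOverlap(
    calls, list(all_ref = calls$gene), n_perm = 100, seed = 7))
  expect_equal(unname(res2$fractions["all", "all_ref"]), 1)
  ## planted high-logFC reference set is enriched
  expect_lt(res$enrichment["up_ref", "p_adj"], 0.05)
})

test_that("GMT round-trips and enforces size bounds", {
  sets <- list(alpha = paste0("g", 1:10), beta = paste0("h", 1:6))
  path <- tempfile(fileext = ".gmt")
  writeGMT(sets, path)
  back <- readGMT(path)
  expect_identical(back, sets)
  expect_length(readGMT(path, min_size = 8), 1)
})
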