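test_that("HLA similarity follows the shared-profile Pearson contract", {
  # no shared peptide -> 0
  net <- binding_network(data.frame(hla = c("A", "A", "B", "B"),
                                    peptide = c("p1", "p2", "p3", "p4"),
                                    weight = c(2L, 1L, 2L, 1L)))
  expect_equal(similarity_hla(net, "A", "B"), 0)

  # self-similarity is 1 when the profile has variance
  net2 <- binding_network(data.frame(hla = "A", peptide = c("p1", "p2"),
                                     weight = c(2L, 1L)))
  expect_equal(similarity_hla(net2, "A", "A"), 1)

  # frozen hand computation: profiles (2,2,1) and (2,1,1) over 3 shared
  # peptides with node means 5/3 and 4/3 give S = 1/2
  net3 <- binding_network(data.frame(
    hla = rep(c("A", "B"), each = 3), peptide = rep(c("p1", "p2", "p3"), 2),
    weight = c(2L, 2L, 1L, 2L, 1L, 1L)))
  expect_equal(similarity_hla(net3, "A", "B"), 0.5)
  expect_equal(similarity_hla(net3, "B", "A"), 0.5)   # symmetric
})

test_that("peptide similarity mirrors the HLA side", {
  net <- binding_network(data.frame(hla = c("A", "B", "A", "B"),
                                    peptide = c("p1", "p1", "p2", "p2"),
                                    weight = c(2L, 1L, 1L, 2L)))
  # anti-correlated two-point profiles (2,1) vs (1,2): S = -1
  expect_equal(similarity_peptide(net, "p1", "p2"), -1)
  # identical profiles with variance: S = 1
  net2 <- binding_network(data.frame(hla = c("A", "B", "A", "B"),
                                     peptide = c("p1", "p1", "p2", "p2"),
                                     weight = c(2L, 1L, 2L, 1L)))
  expect_equal(similarity_peptide(net2, "p1", "p2"), 1)
  # no shared HLA -> 0
  net3 <- binding_network(data.frame(hla = c("A", "A", "B", "B"),
                                     peptide = c("p1", "p2", "p3", "p4"),
                                     weight = c(2L, 1L, 2L, 1L)))
  expect_equal(similarity_peptide(net3, "p1", "p3"), 0)
  expect_true(all(abs(c(similarity_peptide(net, "p1", "p2"),
                        similarity_hla(net, "A", "B"))) <= 1))
})

test_that("predictions match the naive oracle on random small networks", {
  set.seed(1234)
  for (i in 1:100) {
    nh <- sample(2:6, 1); np <- sample(2:6, 1)
    W <- random_weight_matrix(nh, np)
    net <- binding_network(records_from_matrix(W))
    for (dm in c("literal", "absolute")) {
      fit <- nebula(net, denominator = dm)
      pred <- predict(fit, leave_out = TRUE)
      for (r in seq_len(nrow(pred))) {
        i0 <- as.integer(sub("H", "", pred$hla[r]))
        x0 <- as.integer(sub("pep", "", pred$peptide[r]))
        expect_equal(pred$F[r], naive_nebula(W, i0, x0, TRUE, dm),
                     tolerance = 1e-10)
      }
      non <- which(W == 0, arr.ind = TRUE)
      if (nrow(non)) {
        nd <- data.frame(hla = paste0("H", non[, 1]),
                         peptide = paste0("pep", non[, 2]))
        pred2 <- predict(fit, newdata = nd)
        for (r in seq_len(nrow(pred2))) {
          expect_equal(pred2$F[r], naive_nebula(W, non[r, 1], non[r, 2], FALSE, dm),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("degenerate all-constant networks predict the constant", {
  for (w in c(1L, 2L)) {
    recs <- expand.grid(hla = paste0("H", 1:3), peptide = paste0("pep", 1:3),
                        stringsAsFactors = FALSE)
    recs$weight <- w
    fit <- nebula(binding_network(recs))
    pred <- predict(fit, leave_out = TRUE)
    expect_true(all(pred$F == w))
    expect_true(all(pred$C == if (w == 2L) "positive" else "negative"))
    # all similarities degenerate -> node-mean fallback everywhere
    expect_true(all(pred$fallback == "side_mean"))
  }
})

test_that("the unbiased-leverage boundary is inclusive for positive", {
  # construct both sides defined with values 2 and 1 -> F = 1.5 exactly
  fit <- nebula(binding_network(data.frame(hla = "A", peptide = "p1", weight = 2L)))
  fit$global_mean <- 1.5
  p <- predict(fit, newdata = data.frame(hla = "zz", peptide = "qq"))
  expect_equal(p$F, 1.5)
  expect_equal(p$C, "positive")
  # direct threshold law on the returned scores
  net <- binding_network(data.frame(hla = c("A", "A", "B", "B"),
                                    peptide = c("p1", "p2", "p1", "p2"),
                                    weight = c(2L, 1L, 1L, 2L)))
  pred <- predict(nebula(net), leave_out = TRUE)
  expect_identical(pred$C, ifelse(pred$F >= 1.5, "positive", "negative"))
})

test_that("fallback cascade flags missing sides and unknown nodes", {
  # peptide with no other HLA: hla side falls back to the node mean
  net <- binding_network(data.frame(hla = c("A", "A", "B"),
                                    peptide = c("p1", "p2", "p2"),
                                    weight = c(2L, 1L, 2L)))
  fit <- nebula(net)
  p1 <- predict(fit, newdata = data.frame(hla = "A", peptide = "p1"),
                leave_out = TRUE)
  # excluding (A,p1): p1 has no remaining HLA (hla-side node-mean fallback),
  # and p1 has no remaining edges at all (peptide side undefined)
  expect_equal(p1$fallback, "hla_side_only")
  expect_equal(p1$F, 1)   # A's remaining mean
  # both endpoints unknown -> global training mean
  p2 <- predict(fit, newdata = data.frame(hla = "ZZ", peptide = "qqq"))
  expect_equal(p2$fallback, "global_mean")
  expect_equal(p2$F, mean(net$edge_w))
  # known HLA, unknown peptide -> that side's node mean
  p3 <- predict(fit, newdata = data.frame(hla = "A", peptide = "qqq"))
  expect_equal(p3$fallback, "hla_side_only")
  expect_equal(p3$F, 1.5)
})

test_that("consistent relabeling leaves every score unchanged", {
  set.seed(55)
  W <- random_weight_matrix(4, 5)
  recs <- records_from_matrix(W)
  fit1 <- nebula(binding_network(recs))
  pred1 <- predict(fit1, leave_out = TRUE)
  # permute names consistently
  hmap <- setNames(paste0("X", sample(4)), paste0("H", 1:4))
  pmap <- setNames(paste0("q", sample(5)), paste0("pep", 1:5))
  recs2 <- data.frame(hla = hmap[recs$hla], peptide = pmap[recs$peptide],
                      weight = recs$weight)
  fit2 <- nebula(binding_network(recs2))
  pred2 <- predict(fit2, leave_out = TRUE)
  key1 <- paste(hmap[pred1$hla], pmap[pred1$peptide])
  key2 <- paste(pred2$hla, pred2$peptide)
  expect_equal(pred2$F[match(key1, key2)], pred1$F, tolerance = 1e-12)
})

test_that("flipping a neighbor edge positive never lowers P under absolute mode", {
  set.seed(77)
  ok <- 0L
  for (i in 1:50) {
    W <- random_weight_matrix(4, 4)
    tgt <- which(W > 0, arr.ind = TRUE)[1, ]
    i0 <- tgt[1]; x0 <- tgt[2]
    others <- setdiff(which(W[, x0] > 0), i0)
    cand <- others[W[others, x0] == 1L]
    if (!length(cand)) next
    j <- cand[1]
    net1 <- binding_network(records_from_matrix(W))
    fit1 <- nebula(net1, denominator = "absolute")
    # monotonicity is asserted when all neighbor similarities are nonnegative
    sims <- vapply(others, function(jj)
      similarity_hla(net1, paste0("H", i0), paste0("H", jj),
                     exclude = c(paste0("H", i0), paste0("pep", x0))), numeric(1))
    if (any(sims < 0)) next
    W2 <- W; W2[j, x0] <- 2L
    # flipping j's weight changes j's mean, so only require the direct effect:
    # recompute with the flipped network and compare the hla-side value
    p1 <- predict(fit1, newdata = data.frame(hla = paste0("H", i0),
                                             peptide = paste0("pep", x0)),
                  leave_out = TRUE)
    net2 <- binding_network(records_from_matrix(W2))
    sims2 <- vapply(others, function(jj)
      similarity_hla(net2, paste0("H", i0), paste0("H", jj),
                     exclude = c(paste0("H", i0), paste0("pep", x0))), numeric(1))
    if (any(sims2 < 0)) next
    fit2 <- nebula(net2, denominator = "absolute")
    p2 <- predict(fit2, newdata = data.frame(hla = paste0("H", i0),
                                             peptide = paste0("pep", x0)),
                  leave_out = TRUE)
    if (is.na(p1$P_hla) || is.na(p2$P_hla)) next   # side undefined after exclusion
    expect_gte(p2$P_hla, p1$P_hla - 1e-9)
    ok <- ok + 1L
  }
  expect_gte(ok, 5L)   # the property was actually exercised
})

test_that("print and summary report the fit", {
  net <- binding_network(data.frame(hla = c("A", "A", "B", "B"),
                                    peptide = c("p1", "p2", "p1", "p2"),
                                    weight = c(2L, 1L, 1L, 2L)))
  fit <- nebula(net)
  expect_output(print(fit), "unbiased leverage 1.50")
  expect_output(print(summary(fit)), "50.0% positive")
})
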