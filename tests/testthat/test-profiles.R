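test_that("the residue category scheme has the canonical 5/7/8 split", {
  sc <- aa_categories()
  expect_length(sc, 20L)
  expect_equal(sum(sc == "polar_charged"), 5L)
  expect_equal(sum(sc == "polar_uncharged"), 7L)
  expect_equal(sum(sc == "apolar"), 8L)
  expect_setequal(names(sc)[sc == "polar_charged"], c("R", "D", "E", "H", "K"))
})

test_that("length distribution columns sum to 100% and totals balance", {
  sim <- simulate_binding_data(n_modules = 2L, hlas_per_module = 4L,
                               peptides_per_module = 40L, seed = 2)
  net <- binding_network(sim$records[c("hla", "peptide", "label")])
  part <- fast_greedy_modules(net)
  prof <- length_distribution(part, net)
  expect_equal(unname(colSums(prof$percent)), rep(100, ncol(prof$percent)),
               tolerance = 1e-9)
  expect_equal(sum(prof$counts[, "Total"]), length(net$peptide))

  # all 9-mers, two modules of equal size -> 50/50 in the 9-mer column
  recs <- data.frame(
    hla = rep(c("A", "B"), 4),
    peptide = rep(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"), each = 2),
    label = "positive")
  net2 <- binding_network(recs)
  part2 <- list(hla_module = setNames(c(1L, 2L), c("A", "B")),
                peptide_module = setNames(c(1L, 1L, 2L, 2L),
                                          c("AAAAAAAAA", "CCCCCCCCC",
                                            "DDDDDDDDD", "EEEEEEEEE")))
  prof2 <- length_distribution(part2, net2)
  expect_equal(unname(prof2$percent[, "9"]), c(50, 50))

  # single module -> every column 100%
  part3 <- list(hla_module = setNames(c(1L, 1L), c("A", "B")),
                peptide_module = setNames(rep(1L, 4), names(part2$peptide_module)))
  expect_equal(unname(length_distribution(part3, net2)$percent[1, ]), 100)
})

test_that("lengths above 11 pool into one bucket", {
  peps <- c(strrep("A", 9), strrep("C", 12), strrep("D", 14))
  recs <- data.frame(hla = rep(c("A", "B"), 3),
                     peptide = rep(peps, each = 2), label = "positive")
  net <- binding_network(recs)
  part <- list(hla_module = setNames(c(1L, 1L), c("A", "B")),
               peptide_module = setNames(rep(1L, 3), sort(peps)))
  prof <- length_distribution(part, net)
  expect_true(">11" %in% colnames(prof$percent))
  expect_equal(prof$counts[1, ">11"], 2L)
})

test_that("position category profiles count residues correctly", {
  expect_equal(unname(position_category_profile("AAAAAAAAA")["apolar", ]),
               rep(1, 9))
  p <- position_category_profile(c("RRRRRRRRR", "SSSSSSSSS"))
  expect_equal(unname(p["polar_charged", ]), rep(0.5, 9))
  expect_equal(unname(p["polar_uncharged", ]), rep(0.5, 9))
  expect_equal(unname(colSums(p)), rep(1, 9))

  # hand-tallied 10-peptide set at position 2: 4 charged, 3 uncharged, 3 apolar
  peps <- c("ARAAAAAAA", "ADAAAAAAA", "AEAAAAAAA", "AKAAAAAAA",
            "ASAAAAAAA", "ATAAAAAAA", "ANAAAAAAA",
            "ALAAAAAAA", "AVAAAAAAA", "AFAAAAAAA")
  p2 <- position_category_profile(peps)[, "P2"]
  expect_equal(unname(p2[c("polar_charged", "polar_uncharged", "apolar")]),
               c(0.4, 0.3, 0.3))
  expect_error(position_category_profile(c("AAAA", "AAAAAAAAA")), "length")
})

test_that("pseudo-sequences index the aligned region by residue number", {
  aln <- c(X = paste0("KWV", strrep("A", 178)),
           Y = paste0("KWM", strrep("A", 178)))
  cmap <- list("1" = c(2L, 3L), "2" = c(4L, 100L))
  # residue 2 is row position 1
  ps <- extract_pseudo_sequences(aln, cmap, 1)
  expect_equal(unname(ps), c("KW", "KW"))
  ps2 <- extract_pseudo_sequences(aln, cmap, 2)
  expect_equal(unname(ps2), c("VA", "MA"))
  expect_error(extract_pseudo_sequences(aln, list("1" = c(2L, 500L)), 1),
               "500")
  expect_error(extract_pseudo_sequences(aln, cmap, 7), "no contact")
})

test_that("the shipped contact map covers all nine positions in range", {
  cmap <- default_contact_map()
  expect_setequal(names(cmap), as.character(1:9))
  all_res <- unlist(cmap)
  expect_true(all(all_res >= 2 & all_res <= 182))
  expect_true(all(lengths(cmap) >= 1))
})

test_that("pairwise identity is a symmetric match fraction", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("ACDE", "AFDE"), pairwise_identity("AFDE", "ACDE"))
  expect_error(pairwise_identity("AAA", "AAAA"), "equal length")
})

test_that("within vs between identity separates distinct modules", {
  # two modules of internally identical, mutually distinct sequences
  seqs <- c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA", a4 = "AAAA", a5 = "AAAA",
            b1 = "TTTT", b2 = "TTTT", b3 = "TTTT", b4 = "TTTT", b5 = "TTTT")
  mod <- setNames(rep(c(1L, 2L), each = 5), names(seqs))
  res <- within_between_identity(mod, seqs)
  expect_equal(res$mean_within, c(1, 1))
  expect_equal(res$mean_between, c(0, 0))
  expect_true(all(res$p_value < 0.05))

  # all identical: degenerate, NA p
  seqs2 <- setNames(rep("AAAA", length(seqs)), names(seqs))
  res2 <- within_between_identity(mod, seqs2)
  expect_equal(res2$mean_within, res2$mean_between)
  expect_true(all(is.na(res2$p_value)))

  # single-HLA module excluded from testing
  mod3 <- setNames(c(rep(1L, 9), 2L), names(seqs))
  res3 <- within_between_identity(mod3, seqs)
  expect_true(is.na(res3$mean_within[res3$module == 2]))
  expect_true(is.na(res3$p_value[res3$module == 2]))

  # permutation mode agrees on the separable case
  res4 <- within_between_identity(mod, seqs, test = "permutation",
                                  n_perm = 199, seed = 4)
  expect_true(all(res4$p_value < 0.05))
})

test_that("generated alignments separate modules at contact positions", {
  sim <- simulate_hla_alignment(n_modules = 2L, hlas_per_module = 4L,
                                mutation_rate = 0, seed = 6)
  ps <- extract_pseudo_sequences(sim$alignment, sim$contact_map, 2)
  res <- within_between_identity(sim$modules, ps)
  expect_equal(res$mean_within, c(1, 1))   # rate 0: founders exactly
  expect_equal(res$mean_between, c(0, 0))  # full divergence at contacts
  # default preset: within > between with significance
  sim2 <- simulate_hla_alignment(seed = 14)
  ps2 <- extract_pseudo_sequences(sim2$alignment, sim2$contact_map, 9)
  res2 <- within_between_identity(sim2$modules, ps2)
  expect_true(all(res2$mean_within > res2$mean_between))
  expect_true(all(res2$p_value < 0.05))
})

test_that("permuted module labels give roughly uniform identity p-values", {
  sim <- simulate_hla_alignment(n_modules = 2L, hlas_per_module = 5L,
                                mutation_rate = 0.05, seed = 8)
  ps <- extract_pseudo_sequences(sim$alignment, sim$contact_map, 2)
  set.seed(42)
  pvals <- replicate(60, {
    shuf <- setNames(sample(sim$modules), names(sim$modules))
    min(within_between_identity(shuf, ps)$p_value, na.rm = TRUE)
  })
  # under label permutation, small p-values must not dominate
  expect_gt(mean(pvals > 0.05, na.rm = TRUE), 0.5)
})

test_that("non-modal residues are annotated with deterministic tie-breaks", {
  aln <- c(s1 = "AAR", s2 = "AAR", s3 = "ARA")
  ann <- highlight_nonmodal_residues(aln, region_start = 1L)
  # column 1: all A, no annotation; column 2: R in s3; column 3: A in s3
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$allele, c("s3", "s3"))
  expect_equal(ann$residue, c("R", "A"))
  expect_equal(ann$category, c("polar_charged", "apolar"))
  # tie between two residues: alphabetically smallest wins modal status
  aln2 <- c(s1 = "C", s2 = "A")
  ann2 <- highlight_nonmodal_residues(aln2, region_start = 1L)
  expect_equal(ann2$residue, "C")
  # all-identical column yields no rows
  expect_equal(nrow(highlight_nonmodal_residues(c(a = "AA", b = "AA"))), 0L)
})

test_that("alignment FASTA round-trips through Biostrings", {
  sim <- simulate_hla_alignment(n_modules = 2L, hlas_per_module = 2L, seed = 5)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(sim$alignment, f)
  back <- read_hla_alignment(f)
  expect_equal(unname(back), unname(sim$alignment))
  expect_setequal(names(back), names(sim$alignment))
})
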