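#' Parameter presets for the synthetic planted-module generator
#'
#' `"paper_like"` is a desk-scale analogue of a real qualitative Class I
#' binding compilation: 3 planted modules, 21 HLAs x 600 peptides, a mixed
#' 7-13 length distribution dominated by 9-mers, and a marginal positive rate
#' near 40%. `"unit"` is a 4-HLA x 8-peptide network for exercising single
#' operations.
#'
#' @param name `"paper_like"` or `"unit"`.
#' @return Named list of [simulate_binding_data()] arguments.
#' @export
synthetic_preset <- function(name = c("paper_like", "unit")) {
  name <- match.arg(name)
  switch(name,
    paper_like = list(
      n_modules = 3L, hlas_per_module = 7L, peptides_per_module = 200L,
      edge_prob_within = 0.5, edge_prob_between = 0.01,
      pos_rate_within = 0.42, pos_rate_between = 0.10,
      binder_pos_rate = 0.97, nonbinder_pos_rate = 0.03, signal = 1),
    unit = list(
      n_modules = 2L, hlas_per_module = 2L, peptides_per_module = 4L,
      edge_prob_within = 1, edge_prob_between = 0,
      pos_rate_within = 0.5, pos_rate_between = 0.1,
      binder_pos_rate = 1, nonbinder_pos_rate = 0, signal = 1))
}

.default_length_mix <- c("7" = 0.001, "8" = 0.012, "9" = 0.688,
                         "10" = 0.263, "11" = 0.015, "12" = 0.013,
                         "13" = 0.008)

# Default per-module anchor biases (P2, C-terminal position) emulating
# module-specific binding motifs; recycled if n_modules > 3.
.module_biases <- list(
  list(p2 = "apolar",          pomega = "apolar"),
  list(p2 = "polar_charged",   pomega = "polar_uncharged"),
  list(p2 = "polar_uncharged", pomega = "polar_charged"))

#' Generate peptides with position-specific category bias
#'
#' Residues are drawn uniformly over the 20 standard amino acids except at
#' position 2 and the last position, where (with probability `bias`) the
#' residue is drawn uniformly within the requested physicochemical category.
#' With `bias = 1` the anchor category is deterministic.
#'
#' @param n Number of peptides.
#' @param length Peptide length.
#' @param p2_category,pomega_category Category (see [aa_categories()]) favored
#'   at position 2 and the last position; `NULL` for no bias.
#' @param bias Probability of drawing from the favored category.
#' @param scheme Category scheme.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return Character vector of `n` peptides.
#' @export
simulate_peptides <- function(n, length = 9L, p2_category = NULL,
                              pomega_category = NULL, bias = 0.8,
                              scheme = aa_categories(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0L) return(character())
  scheme <- .check_scheme(scheme)
  chars <- matrix(sample(AA_STANDARD, n * length, replace = TRUE),
                  nrow = n, ncol = length)
  apply_bias <- function(col, category) {
    pool <- names(scheme)[scheme == category]
    hit <- stats::runif(n) < bias
    chars[hit, col] <<- sample(pool, sum(hit), replace = TRUE)
  }
  if (!is.null(p2_category) && length >= 2L) apply_bias(2L, p2_category)
  if (!is.null(pomega_category)) apply_bias(length, pomega_category)
  apply(chars, 1, paste, collapse = "")
}

#' Simulate a planted-module HLA-peptide binding dataset
#'
#' Generates a bipartite binding-record set with `n_modules` planted
#' communities. Each peptide belongs to one module and connects to at least
#' two of its module's HLAs (so the default preset survives the degree-2
#' sparsity filter intact), plus further within-module HLAs with probability
#' `edge_prob_within` and cross-module HLAs with probability
#' `edge_prob_between`.
#'
#' Edge labels follow a latent-binder model: a fraction of each module's
#' peptides are cognate binders of their module's alleles. A binder's
#' within-module edges are positive with probability `binder_pos_rate`, a
#' non-binder's with `nonbinder_pos_rate`; the binder fraction is chosen so
#' the marginal within-module positive rate equals `pos_rate_within`.
#' `signal` in \[0, 1\] anneals the binder/non-binder contrast toward zero
#' while preserving that marginal rate: at `signal = 0` labels are
#' independent coin flips at `pos_rate_within` and no predictor can beat
#' chance on within-module edges. Cross-module edges are positive with
#' probability `pos_rate_between`.
#'
#' Peptide sequences carry module-specific anchor-category biases at P2 and
#' the C-terminal position (9-mer motif emulation); by default sequence and
#' label are otherwise uncoupled. Peptide lengths are drawn from
#' `length_mix`.
#'
#' @param n_modules,hlas_per_module,peptides_per_module Planted sizes.
#' @param edge_prob_within Probability of each within-module edge beyond the
#'   two guaranteed per peptide.
#' @param edge_prob_between Probability of each cross-module edge.
#' @param pos_rate_within Marginal positive rate of within-module edges.
#' @param pos_rate_between Positive rate of cross-module edges.
#' @param binder_pos_rate,nonbinder_pos_rate Positive rates of binder /
#'   non-binder peptides at full signal.
#' @param signal Planted-signal strength in \[0, 1\].
#' @param length_mix Named probability vector over peptide lengths.
#' @param anchor_bias Strength of the per-module anchor-category bias.
#' @param seed Integer seed (mandatory).
#' @return List: `records` (hla, peptide, label, weight), `hla_modules` and
#'   `peptide_modules` (named integer vectors of planted labels), `binder`
#'   (named logical), and `spec` (the parameters used).
#' @export
simulate_binding_data <- function(n_modules = 3L, hlas_per_module = 7L,
                                  peptides_per_module = 200L,
                                  edge_prob_within = 0.5,
                                  edge_prob_between = 0.01,
                                  pos_rate_within = 0.42,
                                  pos_rate_between = 0.10,
                                  binder_pos_rate = 0.97,
                                  nonbinder_pos_rate = 0.03,
                                  signal = 1,
                                  length_mix = .default_length_mix,
                                  anchor_bias = 0.8,
                                  seed) {
  stopifnot(!missing(seed), signal >= 0, signal <= 1,
            pos_rate_within >= nonbinder_pos_rate,
            pos_rate_within <= binder_pos_rate)
  set.seed(as.integer(seed))
  nh <- n_modules * hlas_per_module
  np <- n_modules * peptides_per_module
  hla_names <- sprintf("HLA-S%d*%02d:01",
                       rep(seq_len(n_modules), each = hlas_per_module),
                       rep(seq_len(hlas_per_module), n_modules))
  hla_mod <- rep(seq_len(n_modules), each = hlas_per_module)

  # module-biased peptide sequences, resampled until unique
  lens <- sample(as.integer(names(length_mix)), np, replace = TRUE,
                 prob = length_mix)
  pep_mod <- rep(seq_len(n_modules), each = peptides_per_module)
  peps <- character(np)
  for (i in seq_len(np)) {
    b <- .module_biases[[(pep_mod[i] - 1L) %% length(.module_biases) + 1L]]
    repeat {
      s <- simulate_peptides(1L, lens[i], b$p2, b$pomega, bias = anchor_bias)
      if (!s %in% peps[seq_len(i - 1L)]) break
    }
    peps[i] <- s
  }

  # binder fraction reproducing the marginal within-module positive rate
  f <- if (binder_pos_rate > nonbinder_pos_rate)
    (pos_rate_within - nonbinder_pos_rate) / (binder_pos_rate - nonbinder_pos_rate)
  else 0
  binder <- stats::runif(np) < f
  p_binder <- pos_rate_within + signal * (binder_pos_rate - pos_rate_within)
  p_nonbinder <- pos_rate_within + signal * (nonbinder_pos_rate - pos_rate_within)

  eh <- integer(0); ep <- integer(0); ew <- integer(0)
  for (i in seq_len(np)) {
    m <- pep_mod[i]
    own <- which(hla_mod == m)
    picked <- own[stats::runif(length(own)) < edge_prob_within]
    need <- 2L - length(picked)
    if (need > 0L) {
      pool <- setdiff(own, picked)
      extra <- pool[sample.int(length(pool), need)]
      picked <- c(picked, extra)
    }
    foreign <- which(hla_mod != m)
    picked_f <- foreign[stats::runif(length(foreign)) < edge_prob_between]
    p_pos <- c(rep(if (binder[i]) p_binder else p_nonbinder, length(picked)),
               rep(pos_rate_between, length(picked_f)))
    allh <- c(picked, picked_f)
    w <- ifelse(stats::runif(length(allh)) < p_pos, 2L, 1L)
    eh <- c(eh, allh); ep <- c(ep, rep(i, length(allh))); ew <- c(ew, w)
  }
  records <- data.frame(
    hla = hla_names[eh], peptide = peps[ep],
    label = ifelse(ew == 2L, "positive", "negative"),
    weight = ew, stringsAsFactors = FALSE)
  filtered <- degree_filter(records[c("hla", "peptide", "label")])
  if (nrow(filtered) == 0L)
    warning("simulated network is empty after the degree filter (",
            nrow(records), " records generated)")
  list(records = records,
       hla_modules = stats::setNames(hla_mod, hla_names),
       peptide_modules = stats::setNames(pep_mod, peps),
       binder = stats::setNames(binder, peps),
       spec = list(n_modules = n_modules, hlas_per_module = hlas_per_module,
                   peptides_per_module = peptides_per_module,
                   edge_prob_within = edge_prob_within,
                   edge_prob_between = edge_prob_between,
                   pos_rate_within = pos_rate_within,
                   pos_rate_between = pos_rate_between,
                   binder_pos_rate = binder_pos_rate,
                   nonbinder_pos_rate = nonbinder_pos_rate,
                   signal = signal, anchor_bias = anchor_bias, seed = seed))
}

#' Simulate a gapless module-structured HLA alignment
#'
#' Builds one founder sequence per module from a shared base sequence:
#' contact positions (union of the contact map) receive a module-specific
#' residue with probability `contact_divergence`, chosen by cycling the
#' amino-acid alphabet so different modules never share a diverged contact
#' residue; non-contact positions mutate at a low module rate. Each allele is
#' its founder mutated per position at `mutation_rate`. Within-module
#' pseudo-sequence identity therefore exceeds between-module identity, with
#' `mutation_rate = 0` giving within-identity exactly 1 and
#' `contact_divergence = 1` giving between-module contact identity 0.
#'
#' @param n_modules,hlas_per_module Sizes.
#' @param contact_map Contact-residue map, default [default_contact_map()].
#' @param mutation_rate Per-position within-module mutation probability.
#' @param contact_divergence Probability a contact position is module-diverged.
#' @param noncontact_divergence Per-module mutation rate of non-contact
#'   founder positions.
#' @param region_start,region_end Mature-chain residue range covered
#'   (default 2-182, giving 181 columns).
#' @param seed Integer seed (mandatory).
#' @return List: `alignment` (named character vector), `modules` (named
#'   integer), `contact_map`.
#' @export
simulate_hla_alignment <- function(n_modules = 3L, hlas_per_module = 7L,
                                   contact_map = default_contact_map(),
                                   mutation_rate = 0.02,
                                   contact_divergence = 1,
                                   noncontact_divergence = 0.05,
                                   region_start = 2L, region_end = 182L,
                                   seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  width <- region_end - region_start + 1L
  base <- sample(AA_STANDARD, width, replace = TRUE)
  contact_idx <- sort(unique(unlist(contact_map))) - region_start + 1L
  contact_idx <- contact_idx[contact_idx >= 1L & contact_idx <= width]
  base_code <- match(base, AA_STANDARD)

  alleles <- character(0); mods <- integer(0); seqs <- character(0)
  for (m in seq_len(n_modules)) {
    founder <- base
    div <- contact_idx[stats::runif(length(contact_idx)) < contact_divergence]
    # cycle the alphabet so module founders never coincide at diverged sites
    founder[div] <- AA_STANDARD[(base_code[div] + m - 1L) %% 20L + 1L]
    non_contact <- setdiff(seq_len(width), contact_idx)
    flip <- non_contact[stats::runif(length(non_contact)) < noncontact_divergence]
    founder[flip] <- sample(AA_STANDARD, length(flip), replace = TRUE)
    for (a in seq_len(hlas_per_module)) {
      s <- founder
      mut <- which(stats::runif(width) < mutation_rate)
      if (length(mut))
        s[mut] <- vapply(s[mut], function(ch)
          sample(setdiff(AA_STANDARD, ch), 1L), character(1))
      alleles <- c(alleles, sprintf("HLA-S%d*%02d:01", m, a))
      mods <- c(mods, m)
      seqs <- c(seqs, paste(s, collapse = ""))
    }
  }
  list(alignment = stats::setNames(seqs, alleles),
       modules = stats::setNames(mods, alleles),
       contact_map = contact_map)
}

#' Write an alignment as FASTA
#' @param alignment Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(alignment), path)
  invisible(path)
}
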