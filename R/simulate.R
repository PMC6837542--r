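#' Synthetic off-target data with planted position-weighted mismatch penalties
#'
#' Generates random guides and, for each, decoy alignments carrying 0-6
#' substitutions at uniformly chosen positions (matching the at-most-6
#' mismatch convention for candidate off-target sites). The latent activity of
#' a pair is `exp(-sum of position weights at mismatched positions)`, scaled
#' to an indel-frequency range of 0-100%, plus Gaussian noise; binary labels
#' mark the top fraction by [label_top_fraction()]. Larger weights at
#' PAM-proximal (3') positions make mismatches there more damaging, giving a
#' planted, recoverable position ranking.
#'
#' @param n_guides Number of distinct guides.
#' @param decoys_per_guide Aligned decoys generated per guide.
#' @param pair_length Alignment length (20 Cas9 spacer / 27 Cas12a window).
#' @param position_weights Nonnegative penalty per position (length
#'   `pair_length`); default grows quadratically toward the 3' end.
#' @param noise_sd Gaussian noise added to the percent-scale activity.
#' @param label_fraction Top fraction labeled positive. Small values (e.g.
#'   0.004) emulate the severe class imbalance of genome-wide negative mining.
#' @param seed Integer seed; output is reproducible seed-for-seed.
#' @return `offtarget_sim_config()` returns the config list; `gen_offtarget()`
#'   returns a tibble of aligned pairs with columns `sgrna`, `dna`,
#'   `guide_id`, `n_mismatch`, `score` (indel %, 0-100) and `label`.
#' @export
offtarget_sim_config <- function(n_guides = 50, decoys_per_guide = 80,
                                 pair_length = 20,
                                 position_weights = NULL,
                                 noise_sd = 5, label_fraction = 0.2,
                                 seed = 1) {
  L <- as.integer(pair_length)
  position_weights <- position_weights %||% (0.2 + 1.8 * ((seq_len(L)) / L)^2)
  if (length(position_weights) != L || any(position_weights < 0)) {
    abort("`position_weights` must be nonnegative and of length `pair_length`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (label_fraction <= 0 || label_fraction >= 1) abort("`label_fraction` in (0,1).")
  structure(list(n_guides = n_guides, decoys_per_guide = decoys_per_guide,
                 pair_length = L, position_weights = position_weights,
                 noise_sd = noise_sd, label_fraction = label_fraction,
                 seed = as.integer(seed)),
            class = "offtarget_sim_config")
}

#' @rdname offtarget_sim_config
#' @param config An `offtarget_sim_config`.
#' @export
gen_offtarget <- function(config = offtarget_sim_config()) {
  stopifnot(inherits(config, "offtarget_sim_config"))
  bases <- c("A", "C", "G", "T")
  L <- config$pair_length
  withr::with_seed(config$seed, {
    guide_mat <- matrix(sample(bases, config$n_guides * L, replace = TRUE),
                        config$n_guides, L)
    n <- config$n_guides * config$decoys_per_guide
    guide_id <- rep(seq_len(config$n_guides), each = config$decoys_per_guide)
    sg <- guide_mat[guide_id, , drop = FALSE]
    dn <- sg
    n_mm <- sample(0:6, n, replace = TRUE)
    penalty <- numeric(n)
    for (i in seq_len(n)) {
      if (n_mm[i] == 0) next
      posns <- sample.int(L, n_mm[i])
      penalty[i] <- sum(config$position_weights[posns])
      for (p in posns) {
        dn[i, p] <- sample(setdiff(bases, sg[i, p]), 1)
      }
    }
    activity <- 100 * exp(-penalty) + rnorm(n, sd = config$noise_sd)
    activity <- pmin(pmax(activity, 0), 100)
    tibble(
      guide_id = guide_id,
      sgrna = apply(sg, 1, paste, collapse = ""),
      dna = apply(dn, 1, paste, collapse = ""),
      n_mismatch = n_mm,
      score = activity,
      label = label_top_fraction(activity, config$label_fraction)
    )
  })
}

#' Synthetic on-target data with planted dimer and network-mediated effects
#'
#' Builds an Erdos-Renyi gene network with edge confidences from U(0.2, 1),
#' draws a per-cell-line expression profile for each of `cell_lines`, assigns
#' each guide a target gene, and generates guide efficiencies as
#'
#'   efficiency = sum of planted per-(position, dimer) effects
#'              + gene_effect_via_network * NetExpress_z(gene, cell line)
#'              + Gaussian noise,
#'
#' where NetExpress_z is the package's NetExpress score standardized across
#' genes within a cell line (so the coefficient is an effect size in SD
#' units). Because the same guide is emitted once per cell line with
#' cell-line-specific expression, the planted gene-level effect makes guide
#' efficiencies genuinely cell-specific, and NetExpress is informative exactly
#' when `gene_effect_via_network` is nonzero.
#'
#' @param n_guides Guides per cell line.
#' @param seq_length Guide sequence length (20 Cas9 / 34 Cas12a with PAM
#'   context).
#' @param dimer_effects Either a `(seq_length - 1) x 16` matrix of per
#'   (position, dimer) effects, or `NULL` for i.i.d. N(0, `dimer_effect_sd`)
#'   effects at every position.
#' @param dimer_effect_sd SD of randomly drawn dimer effects.
#' @param gene_effect_via_network Coefficient of the standardized NetExpress
#'   score; 0 plants no network-mediated signal.
#' @param n_genes,network_density Gene network size and edge probability.
#' @param cell_lines Character vector of cell line names.
#' @param noise_sd Residual noise SD.
#' @param seed Integer seed.
#' @return `gen_ontarget()` returns a list with `guides` (tibble: `seq`,
#'   `gene`, `cell_line`, `efficiency`, `copy_number`, `netexpress`, and the
#'   standardized `netexpress_z` actually used in the generative formula),
#'   `network` (edge tibble), `expression` (long tibble), and
#'   `dimer_effects` (the planted matrix).
#' @export
ontarget_sim_config <- function(n_guides = 2500, seq_length = 34,
                                dimer_effects = NULL, dimer_effect_sd = 1,
                                gene_effect_via_network = 1,
                                n_genes = 100, network_density = 0.05,
                                cell_lines = c("CL1", "CL2"),
                                noise_sd = 1, seed = 1) {
  L <- as.integer(seq_length)
  if (L < 5) abort("`seq_length` must be at least 5.")
  if (!is.null(dimer_effects) &&
      !(is.matrix(dimer_effects) && all(dim(dimer_effects) == c(L - 1L, 16L)))) {
    abort(sprintf("`dimer_effects` must be a %d x 16 matrix.", L - 1L))
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (network_density <= 0 || network_density > 1) abort("`network_density` in (0,1].")
  structure(list(n_guides = n_guides, seq_length = L,
                 dimer_effects = dimer_effects, dimer_effect_sd = dimer_effect_sd,
                 gene_effect_via_network = gene_effect_via_network,
                 n_genes = as.integer(n_genes), network_density = network_density,
                 cell_lines = cell_lines, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ontarget_sim_config")
}

#' @rdname ontarget_sim_config
#' @param config An `ontarget_sim_config`.
#' @export
gen_ontarget <- function(config = ontarget_sim_config()) {
  stopifnot(inherits(config, "ontarget_sim_config"))
  bases <- c("A", "C", "G", "T")
  L <- config$seq_length
  withr::with_seed(config$seed, {
    genes <- sprintf("G%03d", seq_len(config$n_genes))
    pairs <- utils::combn(config$n_genes, 2)
    keep <- runif(ncol(pairs)) < config$network_density
    if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
    network <- tibble(
      gene_a = genes[pairs[1, keep]],
      gene_b = genes[pairs[2, keep]],
      confidence = runif(sum(keep), 0.2, 1)
    )
    expression <- bind_rows(lapply(config$cell_lines, function(cl) {
      tibble(cell_line = cl, gene = genes,
             value = round(abs(rnorm(config$n_genes, mean = 5, sd = 3)), 3))
    }))
    eff_mat <- config$dimer_effects %||%
      matrix(rnorm((L - 1L) * 16L, sd = config$dimer_effect_sd), L - 1L, 16L)

    # standardized NetExpress per cell line (effect size in SD units);
    # genes with no interactions have an empty neighborhood and score 0
    nx <- netexpress(network, expression)
    all_nx <- tidyr::expand_grid(cell_line = config$cell_lines, gene = genes) %>%
      left_join(nx, by = c("gene", "cell_line")) %>%
      mutate(score = ifelse(is.na(score), 0, score))
    nx <- all_nx %>%
      group_by(cell_line) %>%
      mutate(z = as.numeric(scale(score))) %>%
      ungroup()
    nx$z[!is.finite(nx$z)] <- 0

    seq_mat <- matrix(sample(bases, config$n_guides * L, replace = TRUE),
                      config$n_guides, L)
    seqs <- apply(seq_mat, 1, paste, collapse = "")
    tok <- token_matrix(encode_dimers(seqs))
    seq_term <- rowSums(matrix(
      eff_mat[cbind(rep(seq_len(L - 1L), each = config$n_guides),
                    as.vector(tok) + 1L)],
      config$n_guides, L - 1L))
    gene_of <- sample(genes, config$n_guides, replace = TRUE)
    copy_number <- round(pmax(rnorm(config$n_guides, 2, 0.5), 0.1), 3)

    guides <- bind_rows(lapply(config$cell_lines, function(cl) {
      nxz <- nx$z[match(paste(gene_of, cl), paste(nx$gene, nx$cell_line))]
      nxs <- nx$score[match(paste(gene_of, cl), paste(nx$gene, nx$cell_line))]
      tibble(
        seq = seqs,
        gene = gene_of,
        cell_line = cl,
        copy_number = copy_number,
        netexpress = nxs,
        netexpress_z = nxz,
        efficiency = seq_term + config$gene_effect_via_network * nxz +
          rnorm(config$n_guides, sd = config$noise_sd)
      )
    }))
    list(guides = guides, network = network, expression = expression,
         dimer_effects = eff_mat)
  })
}

#' Tiny hand-checkable fixtures
#'
#' A bundle small enough to verify by hand: a 6-node network containing the
#' path A-B-C with unit weights and unit expression (NetExpress A:1, B:2,
#' C:1), five short guides including the canonical AUGCU dimer example, and
#' one perfectly matched aligned pair.
#'
#' @return A list with `network`, `expression`, `expected_netexpress`,
#'   `guides`, and `pairs`.
#' @export
gen_toy_fixtures <- function() {
  network <- tibble(
    gene_a = c("A", "B", "D", "D"),
    gene_b = c("B", "C", "E", "F"),
    confidence = c(1, 1, 0.5, 0.25)
  )
  expression <- tibble(gene = c("A", "B", "C", "D", "E", "F"),
                       value = c(1, 1, 1, 1, 2, 4))
  expected <- tibble(gene = c("A", "B", "C", "D", "E", "F"),
                     score = c(1, 2, 1, 2, 0.5, 0.25))
  guides <- tibble(
    seq = c("AUGCU", "AAAAA", "ACGTA", "TTTTG", "GCGCG"),
    efficiency = c(1.5, -0.2, 0.7, 0.1, -1.1)
  )
  pairs <- tibble(
    sgrna = c("ACGT", "ACGT"),
    dna = c("ACGT", "ACTT"),
    score = c(90, 10)
  )
  list(network = network, expression = expression,
       expected_netexpress = expected, guides = guides, pairs = pairs)
}
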