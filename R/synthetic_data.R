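#' Configuration for the synthetic miRNA study generator
#'
#' Describes a simulated paired-tissue miRNA profiling study: an array of
#' `n_mirnas` miRNAs measured on log2 scale across `n_pairs` patients, each
#' contributing one normal, one adenoma and one carcinoma sample. A planted
#' set of `n_up` miRNAs is shifted up by `effect_log2fc` in carcinoma (and by
#' `adenoma_effect_frac * effect_log2fc` in adenoma) relative to paired normal
#' tissue; `n_down` miRNAs are shifted down symmetrically. The hub miRNA
#' (miR-155 by default) shares a latent factor with the `corr_group` miRNAs
#' whose loading sign flips between normal and tumour classes, so that within
#' normal samples the hub is negatively correlated with the group and within
#' adenoma/carcinoma samples positively — the sign-switching co-expression
#' structure seen for miR-155 against miR-143/145/192/378 in colorectal
#' tissue series.
#'
#' The defaults emulate an 830-miRNA array over six tissue trios with 40
#' up- and 8 down-regulated miRNAs at |log2FC| = 1.5 and residual noise
#' sd 0.3.
#'
#' @param n_mirnas Number of miRNAs on the array.
#' @param n_pairs Number of patients (paired samples per tissue class).
#' @param n_up,n_down Number of planted up-/down-regulated miRNAs.
#' @param effect_log2fc Planted absolute log2 fold change in carcinoma.
#' @param noise_sd Per-observation Gaussian noise sd on log2 scale.
#' @param hub_mirna Label of the hub miRNA carrying the sign-switching
#'   loading; always included in the planted up set.
#' @param corr_group Labels of miRNAs sharing the latent factor with the hub;
#'   always included in the planted down set (they are the canonical
#'   tumour-suppressor group).
#' @param corr_strength Latent-factor loading magnitude in `[0, 1)`; the
#'   within-class population correlation between hub and each group member is
#'   `-corr_strength` in normal and `+corr_strength` in tumour classes.
#' @param adenoma_effect_frac Fraction of the carcinoma effect applied to
#'   adenoma samples (adenomas are only partially deregulated).
#' @param seed Integer seed; the same seed gives bit-identical output.
#'   Per-component child seeds are derived from it, so extending the
#'   generator never perturbs earlier draws.
#' @return A list of class `simulation_config`.
#' @seealso [simulate_expression()], [simulate_annotations()]
#' @export
simulation_config <- function(n_mirnas = 830, n_pairs = 6, n_up = 40,
                              n_down = 8, effect_log2fc = 1.5, noise_sd = 0.3,
                              hub_mirna = "hsa-miR-155",
                              corr_group = c("hsa-miR-143", "hsa-miR-145",
                                             "hsa-miR-192", "hsa-miR-378"),
                              corr_strength = 0.8,
                              adenoma_effect_frac = 0.5, seed = 1) {
  if (!is_count(n_mirnas) || n_mirnas < 1) abort("n_mirnas must be a positive integer")
  if (!is_count(n_pairs) || n_pairs < 1) abort("n_pairs must be a positive integer")
  if (!is_count(n_up) || !is_count(n_down)) abort("n_up/n_down must be nonnegative integers")
  if (n_up + n_down > n_mirnas) abort("n_up + n_down cannot exceed n_mirnas")
  if (!is.numeric(effect_log2fc) || effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.numeric(corr_strength) || corr_strength < 0 || corr_strength >= 1) {
    abort("corr_strength must lie in [0, 1)")
  }
  if (!is_string(hub_mirna)) abort("hub_mirna must be a single label")
  corr_group <- as.character(corr_group)
  if (hub_mirna %in% corr_group) abort("hub_mirna cannot be a member of corr_group")
  if (!is.numeric(adenoma_effect_frac) || adenoma_effect_frac < 0 ||
      adenoma_effect_frac > 1) {
    abort("adenoma_effect_frac must lie in [0, 1]")
  }
  if (!is_count(abs(seed))) abort("seed must be an integer")
  # named miRNAs need room among the planted sets
  if (n_up < 1) abort("n_up must be >= 1 (the hub miRNA is planted up)")
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_pairs = as.integer(n_pairs),
    n_up = as.integer(n_up), n_down = as.integer(n_down),
    effect_log2fc = effect_log2fc, noise_sd = noise_sd,
    hub_mirna = hub_mirna, corr_group = corr_group,
    corr_strength = corr_strength,
    adenoma_effect_frac = adenoma_effect_frac, seed = as.integer(seed)
  ), class = "simulation_config")
}

# miRNA labels and the planted regulation sets for a config. The hub miRNA
# leads the up set; the corr_group miRNAs lead the down set (truncated if
# n_down is smaller), matching the biology the generator emulates: miR-155 up,
# miR-143/145/192/378 down in carcinoma.
planted_labels <- function(config) {
  named <- c(config$hub_mirna, config$corr_group)
  n_generic <- config$n_mirnas - length(named)
  if (n_generic < 0) abort("n_mirnas too small for the named miRNAs")
  generic <- sprintf("hsa-miR-sim-%04d", seq_len(n_generic))
  labels <- c(named, generic)
  up <- c(config$hub_mirna, head(generic, config$n_up - 1L))
  down_named <- head(config$corr_group, config$n_down)
  n_down_extra <- config$n_down - length(down_named)
  down <- c(down_named,
            generic[seq_len(n_down_extra) + (config$n_up - 1L)])
  if (length(up) < config$n_up || length(down) < config$n_down) {
    abort("not enough miRNAs to host the planted up/down sets")
  }
  list(labels = labels, up = up, down = down)
}

#' Simulate a paired-tissue miRNA expression matrix
#'
#' Generates log2 expression values directly: each miRNA gets a baseline mean
#' drawn uniformly on `[4, 12]`, the planted sets get their class-specific
#' shifts, and Gaussian residuals of sd `noise_sd` are added per observation.
#' The sign-switching correlation is produced by a shared latent factor: the
#' hub miRNA's residual is the (scaled) factor itself, with its loading sign
#' flipped to negative in normal samples, while each `corr_group` member mixes
#' the factor (loading `corr_strength`) with independent noise. Residual
#' variance is identical for every miRNA, so the correlation structure does
#' not alter the power of the downstream paired test.
#'
#' @param config A [simulation_config()].
#' @return An [expression_matrix()] with `n_mirnas` rows and
#'   `3 * n_pairs` columns and metadata recording tissue class and pair id.
#' @examples
#' expr <- simulate_expression(simulation_config(n_mirnas = 50, seed = 7))
#' dim(expr$values)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lab <- planted_labels(config)
  classes <- tissue_classes()
  n_m <- config$n_mirnas
  n_p <- config$n_pairs
  pair_ids <- sprintf("p%02d", seq_len(n_p))
  metadata <- data.frame(
    tissue_class = rep(classes, each = n_p),
    pair_id = rep(pair_ids, times = 3L),
    stringsAsFactors = FALSE
  )
  metadata$sample_id <- paste(metadata$tissue_class, metadata$pair_id, sep = "_")
  metadata <- metadata[, c("sample_id", "tissue_class", "pair_id")]

  set.seed(child_seed(config$seed, "expression"))
  baseline <- runif(n_m, 4, 12)
  z <- array(rnorm(n_m * 3L * n_p), dim = c(n_m, 3L, n_p))

  eff <- matrix(0, n_m, 3L, dimnames = list(lab$labels, classes))
  up_i <- match(lab$up, lab$labels)
  dn_i <- match(lab$down, lab$labels)
  eff[up_i, "carcinoma"] <- config$effect_log2fc
  eff[up_i, "adenoma"] <- config$effect_log2fc * config$adenoma_effect_frac
  eff[dn_i, "carcinoma"] <- -config$effect_log2fc
  eff[dn_i, "adenoma"] <- -config$effect_log2fc * config$adenoma_effect_frac

  hub_i <- match(config$hub_mirna, lab$labels)
  grp_i <- match(config$corr_group, lab$labels)
  cs <- config$corr_strength
  resid <- z # overwritten for hub and group rows
  # The hub residual is the latent factor itself, with loading -1 in normal
  # and +1 in tumour classes; each group member mixes the factor (loading
  # corr_strength) with its own noise. With only a handful of samples per
  # class a population correlation would be realised very noisily, so the
  # loading is realised exactly: the factor is standardised within each
  # class and the member noise is orthogonalised against it in-sample,
  # making the within-class sample correlation between hub and member
  # exactly -corr_strength (normal) or +corr_strength (tumour). A side
  # effect is that these residuals have zero within-class mean, so the
  # planted fold changes of the hub and group miRNAs are recovered exactly.
  # Needs >= 3 pairs; below that the raw mixture is used.
  cls_sign <- c(normal = -1, adenoma = 1, carcinoma = 1)
  for (ci in seq_along(classes)) {
    f <- z[hub_i, ci, ] # latent factor values, one per pair within class
    exact <- n_p >= 3L && sd(f) > 0
    if (exact) f <- (f - mean(f)) / sd(f)
    resid[hub_i, ci, ] <- cls_sign[[classes[ci]]] * f
    for (gi in grp_i) {
      e <- z[gi, ci, ]
      if (exact) {
        e <- e - mean(e) - (sum(e * f) / sum(f * f)) * f
        if (sd(e) > 0) e <- e / sd(e)
      }
      resid[gi, ci, ] <- cs * f + sqrt(1 - cs^2) * e
    }
  }

  values <- matrix(NA_real_, n_m, 3L * n_p,
                   dimnames = list(lab$labels, metadata$sample_id))
  for (ci in seq_along(classes)) {
    cols <- which(metadata$tissue_class == classes[ci])
    values[, cols] <- baseline + eff[, ci] +
      config$noise_sd * matrix(resid[, ci, ], n_m, n_p)
  }
  out <- expression_matrix(values, metadata)
  attr(out, "planted") <- lab[c("up", "down")]
  attr(out, "config") <- config
  out
}

#' Simulate miRNA target, pathway and TF annotation tables
#'
#' Builds an annotation bundle with the structure the enrichment and network
#' stages assume: a pathway database over a finite gene universe, a
#' miRNA-to-target map in which every planted differential miRNA's target set
#' is strongly enriched for a small number of "signal" pathways, and a
#' TF-to-miRNA regulation map. The bundle is engineered so that the hub miRNA
#' shares at least one enriched pathway with every other planted miRNA (its
#' signal pathways are the pool the others draw their first signal pathway
#' from), making it the top hub of the pathway-synergy network, and it always
#' contains the literature-anchored regulator edges SMAD3 -> hub,
#' SMAD4 -> hub and CEBPB -> first corr_group member.
#'
#' @param config A [simulation_config()]; determines the annotated miRNAs.
#' @param n_genes Size of the gene symbol pool pathways are drawn from.
#' @param n_pathways Number of pathway gene sets.
#' @param seed Seed; defaults to the config seed (a child seed is derived).
#' @param pathway_size Integer range (min, max) of pathway sizes.
#' @param signal_frac Fraction of a signal pathway's genes included in the
#'   targeting miRNA's target set.
#' @param n_hub_pathways Number of signal pathways assigned to the hub.
#' @return A list of class `annotation_bundle` with elements `target_map`
#'   (miRNA -> character vector of gene symbols), `pathway_db` (pathway id ->
#'   gene set), `pathway_desc` (pathway id -> description), `tf_map` (TF ->
#'   regulated miRNAs) and `universe` (the full gene pool).
#' @export
simulate_annotations <- function(config, n_genes = 2000, n_pathways = 50,
                                 seed = config$seed,
                                 pathway_size = c(15L, 60L),
                                 signal_frac = 0.7, n_hub_pathways = 6L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(n_genes) || n_genes < 1) abort("n_genes must be positive")
  if (!is_count(n_pathways) || n_pathways < 1) abort("n_pathways must be positive")
  if (length(pathway_size) != 2L || pathway_size[1] > pathway_size[2]) {
    abort("pathway_size must be an increasing (min, max) pair")
  }
  if (n_genes < pathway_size[2]) {
    abort(sprintf(
      "infeasible annotation constraint: gene pool (%d) smaller than the largest requested pathway (%d)",
      n_genes, pathway_size[2]), "crcmirnet_infeasible_error")
  }
  lab <- planted_labels(config)
  de_mirnas <- c(lab$up, lab$down)

  set.seed(child_seed(seed, "annotations"))
  universe <- sprintf("G%05d", seq_len(n_genes))
  pw_ids <- sprintf("PW%03d", seq_len(n_pathways))
  sizes <- sample(seq(pathway_size[1], pathway_size[2]), n_pathways,
                  replace = TRUE)
  pathway_db <- setNames(lapply(sizes, function(s) sort(sample(universe, s))),
                         pw_ids)
  pathway_desc <- setNames(sprintf("synthetic pathway %s", pw_ids), pw_ids)
  pool <- sort(unique(unlist(pathway_db, use.names = FALSE)))

  hub_pws <- pw_ids[seq_len(min(n_hub_pathways, n_pathways))]
  other_pws <- setdiff(pw_ids, hub_pws)
  signal_sets <- setNames(vector("list", length(de_mirnas)), de_mirnas)
  signal_sets[[config$hub_mirna]] <- hub_pws
  for (m in setdiff(de_mirnas, config$hub_mirna)) {
    first <- sample(hub_pws, 1L) # guarantees a pathway shared with the hub
    second <- if (length(other_pws)) sample(other_pws, 1L) else character(0)
    signal_sets[[m]] <- c(first, second)
  }
  target_map <- lapply(signal_sets, function(pws) {
    sig <- unlist(lapply(pathway_db[pws], function(g) {
      sample(g, max(1L, round(signal_frac * length(g))))
    }), use.names = FALSE)
    bg <- sample(pool, min(20L, length(pool)))
    sort(unique(c(sig, bg)))
  })

  named_tfs <- list(
    SMAD3 = config$hub_mirna,
    SMAD4 = config$hub_mirna,
    CEBPB = if (length(config$corr_group)) config$corr_group[1] else config$hub_mirna
  )
  n_tf <- 10L
  random_tfs <- setNames(
    lapply(seq_len(n_tf), function(i) {
      sort(sample(de_mirnas, sample(3:8, 1L)))
    }),
    sprintf("TF%02d", seq_len(n_tf))
  )
  tf_map <- c(named_tfs, random_tfs)

  structure(list(target_map = target_map, pathway_db = pathway_db,
                 pathway_desc = pathway_desc, tf_map = tf_map,
                 universe = universe),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "annotation_bundle: %d miRNAs with targets, %d pathways, %d TFs, %d-gene universe\n",
    length(x$target_map), length(x$pathway_db), length(x$tf_map),
    length(x$universe)))
  invisible(x)
}

#' Simulate a 2x2 marker-positivity table
#'
#' Draws `n` subjects with a binary exposure (e.g. TGF-beta1 positivity) and a
#' binary marker (e.g. B7-H3 positivity) whose conditional distribution is set
#' so the population odds ratio equals `odds_ratio`, then tabulates joint
#' counts.
#'
#' @param n Number of subjects.
#' @param p_exposure Marginal probability of exposure positivity.
#' @param odds_ratio Population odds ratio of marker given exposure.
#' @param seed Integer seed.
#' @param p_marker_unexposed Probability of marker positivity among the
#'   unexposed (the baseline the odds ratio is applied to).
#' @return A [contingency_2x2()] with cells a (exp+/marker+),
#'   b (exp-/marker+), c (exp+/marker-), d (exp-/marker-) summing to `n`.
#' @examples
#' simulate_positivity(78, p_exposure = 0.47, odds_ratio = 2.96, seed = 1)
#' @export
simulate_positivity <- function(n, p_exposure, odds_ratio, seed,
                                p_marker_unexposed = 0.5) {
  if (!is_count(n) || n < 1) abort("n must be a positive integer")
  if (!is.numeric(p_exposure) || p_exposure <= 0 || p_exposure >= 1) {
    abort("p_exposure must lie strictly in (0, 1)")
  }
  if (!is.numeric(odds_ratio) || odds_ratio <= 0) {
    abort("odds_ratio must be positive")
  }
  if (!is.numeric(p_marker_unexposed) || p_marker_unexposed <= 0 ||
      p_marker_unexposed >= 1) {
    abort("p_marker_unexposed must lie strictly in (0, 1)")
  }
  set.seed(child_seed(seed, "positivity"))
  odds0 <- p_marker_unexposed / (1 - p_marker_unexposed)
  p1 <- odds_ratio * odds0 / (1 + odds_ratio * odds0)
  exposure <- rbinom(n, 1L, p_exposure)
  marker <- rbinom(n, 1L, ifelse(exposure == 1L, p1, p_marker_unexposed))
  contingency_2x2(
    a = sum(exposure == 1L & marker == 1L),
    b = sum(exposure == 0L & marker == 1L),
    c = sum(exposure == 1L & marker == 0L),
    d = sum(exposure == 0L & marker == 0L)
  )
}
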