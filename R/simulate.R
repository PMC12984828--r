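#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulation helpers never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Simulate a random binary phylogeny
#'
#' Coalescent-style random binary topology with exponential branch lengths
#' (mean 0.1), leaves named `taxon_0001`, `taxon_0002`, ...
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed; the same seed always yields the same Newick
#'   string.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rtree(n_taxa, rooted = TRUE,
                                     br = function(k) stats::rexp(k, rate = 10)))
  tree$tip.label <- sprintf("taxon_%04d", seq_len(n_taxa))
  tree
}

#' Configuration for a multi-study cohort simulation
#'
#' Captures the generative conditions: study sizes, planted disease effects,
#' per-study batch shifts, sequencing depth and its overdispersion.
#'
#' @param n_taxa Number of taxa.
#' @param studies List of lists, each `list(study_id=, n_case=, n_control=)`.
#' @param effect_taxa Named numeric vector of planted log-fold effects
#'   (latent log-abundance scale) for disease samples; names must be taxa.
#'   `NULL` = no planted effect.
#' @param batch_shift_sd SD of the per-study, per-taxon location shift on
#'   the latent log scale.
#' @param batch_scale_sd SD of the per-study, per-taxon log scale
#'   perturbation of the latent noise.
#' @param fixed_batch_shift Optional named list `study_id -> shift` (scalar
#'   or per-taxon vector) replacing random shift draws for those studies.
#' @param sequencing_depth_mean Mean reads per sample.
#' @param overdispersion Log-normal sigma of the per-sample depth.
#' @param corr_length Length-scale of the tree-structured latent covariance
#'   `exp(-d / corr_length)`.
#' @param seed Integer RNG seed; fixed seed implies bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 100,
                       studies = list(list(study_id = "s1", n_case = 50,
                                           n_control = 50)),
                       effect_taxa = NULL,
                       batch_shift_sd = 0,
                       batch_scale_sd = 0,
                       fixed_batch_shift = NULL,
                       sequencing_depth_mean = 10000,
                       overdispersion = 0.3,
                       corr_length = 1.0,
                       seed = 1L) {
  ids <- vapply(studies, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id in `studies`")
  if (batch_shift_sd < 0 || batch_scale_sd < 0 || overdispersion < 0)
    stop("SDs must be >= 0")
  if (sequencing_depth_mean <= 0) stop("sequencing_depth_mean must be > 0")
  structure(list(n_taxa = n_taxa, studies = studies,
                 effect_taxa = effect_taxa,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd,
                 fixed_batch_shift = fixed_batch_shift,
                 sequencing_depth_mean = sequencing_depth_mean,
                 overdispersion = overdispersion,
                 corr_length = corr_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default multi-study benchmark configuration
#'
#' Five case-control studies whose case/control counts mirror a typical
#' public gut-microbiome case-control collection (Crohn's, colorectal
#' cancer, HIV, obesity, C. difficile; 94-433 samples per arm) scaled by
#' 0.2 for tractable runtimes; 100 tree-correlated taxa; five planted
#' disease-associated taxa at log-fold +1.5; per-study batch shifts of SD
#' 1.0 on the latent log scale.
#'
#' @param seed Integer seed governing both the planted-taxon choice and the
#'   data draw.
#' @param effect Log-fold effect of the planted taxa.
#' @param n_effect Number of planted taxa.
#' @param batch_shift_sd Per-study, per-taxon latent location-shift SD.
#' @return A `sim_config`.
#' @export
benchmark_config <- function(seed = 42L, effect = 1.5, n_effect = 5,
                             batch_shift_sd = 1.0) {
  studies <- list(
    list(study_id = "ibd_a", n_case = 45, n_control = 6),
    list(study_id = "crc_b", n_case = 24, n_control = 34),
    list(study_id = "hiv_c", n_case = 41, n_control = 7),
    list(study_id = "ob_d",  n_case = 37, n_control = 87),
    list(study_id = "cdi_e", n_case = 19, n_control = 31))
  taxa <- sprintf("taxon_%04d", seq_len(100))
  planted <- with_seed(seed + 1000L, sample(taxa, n_effect))
  effects <- stats::setNames(rep(effect, n_effect), planted)
  sim_config(n_taxa = 100, studies = studies, effect_taxa = effects,
             batch_shift_sd = batch_shift_sd, batch_scale_sd = 0.2,
             sequencing_depth_mean = 10000, overdispersion = 0.3,
             corr_length = 1.0, seed = seed)
}

softmax_vec <- function(y) {
  e <- exp(y - max(y))
  e / sum(e)
}

#' Simulate multi-study case-control cohorts
#'
#' Generative model per sample: latent log-abundances are a taxon base
#' level plus a tree-correlated multivariate normal draw (covariance
#' `exp(-d / corr_length)` over patristic distances), plus the planted
#' disease effect for cases and the study's location/scale batch
#' perturbation; the latent vector is closed by softmax into a composition
#' and counts are drawn multinomially at a log-normal per-sample depth.
#'
#' @param config A [sim_config()].
#' @param tree An `ape::phylo` with at least `config$n_taxa` leaves.
#' @return List with `counts` ([count_table()]), `meta`
#'   (`sample_metadata`) and `truth` (planted effects, per-study batch
#'   shift/scale matrices, per-sample depths).
#' @export
simulate_cohorts <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"))
  validate_tree(tree)
  if (length(tree$tip.label) < config$n_taxa)
    stop("tree has fewer leaves than config$n_taxa")
  taxa <- tree$tip.label[seq_len(config$n_taxa)]
  if (!is.null(config$effect_taxa) &&
      !all(names(config$effect_taxa) %in% taxa))
    stop("effect_taxa not a subset of the simulated taxa")

  d <- patristic_distances(ape::keep.tip(tree, taxa))[taxa, taxa]
  Sigma <- exp(-d / config$corr_length)
  R <- chol(Sigma + diag(1e-8, nrow(Sigma)))

  n_taxa <- length(taxa)
  study_ids <- vapply(config$studies, `[[`, "", "study_id")
  effects <- stats::setNames(numeric(n_taxa), taxa)
  if (!is.null(config$effect_taxa))
    effects[names(config$effect_taxa)] <- config$effect_taxa

  with_seed(config$seed, {
    base_mu <- stats::rnorm(n_taxa, 0, 1)
    shift <- matrix(stats::rnorm(n_taxa * length(study_ids),
                                 0, config$batch_shift_sd),
                    nrow = n_taxa, dimnames = list(taxa, study_ids))
    lscale <- matrix(stats::rnorm(n_taxa * length(study_ids),
                                  0, config$batch_scale_sd),
                     nrow = n_taxa, dimnames = list(taxa, study_ids))
    if (!is.null(config$fixed_batch_shift)) {
      for (sid in names(config$fixed_batch_shift))
        shift[, sid] <- config$fixed_batch_shift[[sid]]
    }
    scale_fac <- exp(lscale)

    n_total <- sum(vapply(config$studies,
                          function(s) s$n_case + s$n_control, 0))
    counts <- matrix(0, nrow = n_taxa, ncol = n_total,
                     dimnames = list(taxa, NULL))
    sample_id <- character(n_total)
    study_col <- character(n_total)
    label_col <- character(n_total)
    depths <- numeric(n_total)
    meanlog <- log(config$sequencing_depth_mean) - config$overdispersion^2 / 2

    j <- 0L
    for (s in config$studies) {
      sid <- s$study_id
      for (lab in c(rep("disease", s$n_case), rep("control", s$n_control))) {
        j <- j + 1L
        z <- stats::rnorm(n_taxa)
        noise <- as.vector(crossprod(R, z)) * scale_fac[, sid]
        y <- base_mu + shift[, sid] + noise
        if (lab == "disease") y <- y + effects
        depth <- max(100, round(stats::rlnorm(1, meanlog,
                                              config$overdispersion)))
        counts[, j] <- stats::rmultinom(1, depth, softmax_vec(y))
        depths[j] <- depth
        sample_id[j] <- sprintf("%s_%s_%03d", sid,
                                substr(lab, 1, 3), j)
        study_col[j] <- sid
        label_col[j] <- lab
      }
    }
    colnames(counts) <- sample_id
    meta <- validate_metadata(data.frame(sample_id = sample_id,
                                         study_id = study_col,
                                         label = label_col,
                                         stringsAsFactors = FALSE))
    list(counts = count_table(counts), meta = meta,
         truth = list(effects = effects, batch_shift = shift,
                      batch_scale = scale_fac, depths = depths))
  })
}

#' CLR-space batch fixture with an exactly planted location shift
#'
#' Estimator-validation fixture for the harmonization stage: samples are
#' i.i.d. CLR vectors (tree-free standard normal deviations around a taxon
#' base level, centered per sample), and the stated constant is then added
#' to every taxon of the shifted studies directly in CLR space -- the space
#' in which the location-scale correction operates. A constant latent-space
#' shift on all taxa would cancel under compositional closure, so planting
#' in CLR space is the only way to realize an exact known shift.
#'
#' @param n_per_study Samples per study.
#' @param n_taxa Number of taxa.
#' @param shift Named numeric vector `study_id -> CLR shift` (first study
#'   conventionally 0).
#' @param seed Integer seed.
#' @return List with `X` (taxa x samples CLR-mode matrix) and `meta`.
#' @export
simulate_batch_fixture <- function(n_per_study = 100, n_taxa = 50,
                                   shift = c(batch1 = 0, batch2 = 1),
                                   seed = 42L) {
  studies <- names(shift)
  with_seed(seed, {
    base <- stats::rnorm(n_taxa, 0, 1)
    n <- n_per_study * length(studies)
    X <- matrix(0, n_taxa, n,
                dimnames = list(sprintf("taxon_%04d", seq_len(n_taxa)),
                                sprintf("smp_%03d", seq_len(n))))
    study_col <- rep(studies, each = n_per_study)
    for (j in seq_len(n)) {
      v <- base + stats::rnorm(n_taxa)
      v <- v - mean(v)                      # CLR zero-sum
      X[, j] <- v + shift[[study_col[j]]]
    }
    meta <- validate_metadata(data.frame(sample_id = colnames(X),
                                         study_id = study_col,
                                         label = "control",
                                         stringsAsFactors = FALSE))
    list(X = composition_matrix(X, mode = "clr", validate = FALSE),
         meta = meta)
  })
}

#' Simulate amplicon reads under the exponential-decay error model
#'
#' Reads are drawn from `true_seqs` proportionally to `abundances`;
#' per-base Phred scores come from a clipped normal quality profile; with
#' probability `exp(-error_alpha * Q)` a base is re-drawn uniformly from
#' {A,C,G,T} (so the per-base mismatch rate is 3/4 of the error
#' probability).
#'
#' @param true_seqs Character vector of source sequences (equal length not
#'   required).
#' @param abundances Relative abundances of the sources (sum to 1).
#' @param depth Number of reads.
#' @param error_alpha Decay rate of error likelihood per Phred unit
#'   (> 0); `log(10)/10` makes `exp(-alpha*Q)` the standard Phred error
#'   probability.
#' @param seed Integer seed.
#' @param quality_mean,quality_sd Normal quality profile, clipped to
#'   `[quality_min, 41]`.
#' @param quality_min Lower clip for Phred scores.
#' @return List with `reads` ([read_set()]) and `truth` (integer source
#'   index per read).
#' @export
simulate_reads <- function(true_seqs, abundances, depth,
                           error_alpha = log(10) / 10, seed = 1L,
                           quality_mean = 30, quality_sd = 3,
                           quality_min = 2) {
  if (length(true_seqs) == 0) stop("true_seqs is empty")
  if (error_alpha <= 0) stop("error_alpha must be > 0")
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    src <- sample.int(length(true_seqs), depth, replace = TRUE,
                      prob = abundances)
    seqs <- character(depth)
    quals <- vector("list", depth)
    for (r in seq_len(depth)) {
      s <- strsplit(true_seqs[src[r]], "")[[1]]
      L <- length(s)
      q <- pmin(41L, pmax(as.integer(quality_min),
                          as.integer(round(stats::rnorm(L, quality_mean,
                                                        quality_sd)))))
      perr <- exp(-error_alpha * q)
      flip <- stats::runif(L) < perr
      if (any(flip)) s[flip] <- sample(bases, sum(flip), replace = TRUE)
      seqs[r] <- paste(s, collapse = "")
      quals[[r]] <- q
    }
    list(reads = read_set(sprintf("read_%06d", seq_len(depth)), seqs, quals),
         truth = src)
  })
}

#' Construct a two-parent chimeric splice
#'
#' Left segment from `seq_a`, right segment from `seq_b`, joined at
#' `split` (the last position taken from `seq_a`). Fixture generator for
#' chimera-removal tests.
#'
#' @param seq_a,seq_b Parent sequences of equal length.
#' @param split Split point, `1 <= split < nchar(seq_a)`.
#' @return Character chimeric sequence.
#' @export
splice_chimera <- function(seq_a, seq_b, split) {
  stopifnot(nchar(seq_a) == nchar(seq_b), split >= 1, split < nchar(seq_a))
  paste0(substr(seq_a, 1, split), substr(seq_b, split + 1, nchar(seq_b)))
}
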