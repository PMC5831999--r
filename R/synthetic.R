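#' Describe a planted co-expression module
#'
#' A planted module is a set of genes sharing a latent factor (and, when the
#' members also carry a planted fold-change, a shared sepsis response) such
#' that the expected pairwise correlation of the members over the pooled
#' samples of an active age group equals `latent_cor`. A module active in
#' exactly one age group is, by construction, differentially connected
#' between the two age-group networks.
#'
#' Members listed in `lnc_members` are labelled lncRNA and receive reduced
#' unique noise (`noise_sd * hub_noise_factor`) in the samples of the
#' module's active age groups, which makes them more correlated with every
#' other member than members are with one another: they are the module's
#' planted hubs. In inactive age groups (where the module does not exist)
#' they keep the full `noise_sd`.
#'
#' @param gene_ids Character vector of member gene ids.
#' @param latent_cor Target within-module pairwise correlation, in (0, 1].
#' @param active_groups Subset of `c("adult", "elderly")` in which the shared
#'   factor is present.
#' @param lnc_members Subset of `gene_ids` labelled lncRNA (the planted hubs).
#' @param hub_noise_factor Multiplier on `noise_sd` for the unique noise of
#'   `lnc_members` (default 0.5).
#' @return A `PlantedModule` list.
#' @export
planted_module <- function(gene_ids, latent_cor, active_groups,
                           lnc_members = character(0),
                           hub_noise_factor = 0.5) {
  stopifnot(length(gene_ids) >= 2,
            is.numeric(latent_cor), latent_cor > 0, latent_cor <= 1,
            all(active_groups %in% AGE_GROUPS), length(active_groups) >= 1,
            all(lnc_members %in% gene_ids),
            hub_noise_factor > 0)
  structure(list(gene_ids = as.character(gene_ids), latent_cor = latent_cor,
                 active_groups = active_groups,
                 lnc_members = as.character(lnc_members),
                 hub_noise_factor = hub_noise_factor),
            class = "PlantedModule")
}

#' Describe a planted differential-expression effect
#'
#' @param gene_ids Character vector of affected gene ids.
#' @param log2fc Log2 fold-change added to the sepsis samples of the stated
#'   age groups (sepsis/control ratio on the linear scale is `2^log2fc`).
#' @param age_groups Subset of `c("adult", "elderly")`.
#' @return A `DegEffect` list.
#' @export
deg_effect <- function(gene_ids, log2fc, age_groups) {
  stopifnot(is.numeric(log2fc), length(log2fc) == 1,
            all(age_groups %in% AGE_GROUPS))
  structure(list(gene_ids = as.character(gene_ids), log2fc = log2fc,
                 age_groups = age_groups),
            class = "DegEffect")
}

#' Configuration for the synthetic expression generator
#'
#' @param n_genes Total number of genes.
#' @param n_per_cell Subjects per design cell (age group x status), >= 2
#'   (default 6, the study design).
#' @param modules List of [planted_module()] objects.
#' @param deg_effects List of [deg_effect()] objects.
#' @param noise_sd Standard deviation of the log2-ratio noise (> 0).
#' @param baseline_sd Standard deviation of the per-gene baseline log2
#'   ratio shared by all samples (the tissue-vs-reference profile of a
#'   two-colour design; default 1). It cancels in all group contrasts and
#'   gene-gene correlations but gives samples the correlated baseline that
#'   real ratio profiles have.
#' @param background_detect_rate Probability that a background (unplanted)
#'   gene is fully detected; undetected background genes get sporadic flags
#'   at rate `stray_flag_rate`.
#' @param stray_flag_rate Per-sample flag probability for undetected
#'   background genes (default 0.3).
#' @param classes Optional character vector (length `n_genes`) of gene
#'   classes; defaults to `protein_coding` except module `lnc_members`,
#'   which are always forced to `lncRNA`.
#' @param allow_overlap Allow a gene to belong to several modules
#'   (default FALSE; overlap otherwise raises an error naming the gene).
#' @param seed Integer seed; part of the config, never hidden global state.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes, n_per_cell = 6, modules = list(),
                             deg_effects = list(), noise_sd = 0.5,
                             baseline_sd = 1,
                             background_detect_rate = 0.25,
                             stray_flag_rate = 0.3,
                             classes = NULL, allow_overlap = FALSE,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_per_cell >= 2, noise_sd > 0, baseline_sd >= 0,
            background_detect_rate >= 0, background_detect_rate <= 1)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(classes)) {
    classes <- rep("protein_coding", n_genes)
  }
  stopifnot(length(classes) == n_genes,
            all(classes %in% setdiff(PROBE_CLASSES, "excluded")))
  names(classes) <- gene_ids
  for (m in modules) {
    stopifnot(inherits(m, "PlantedModule"), all(m$gene_ids %in% gene_ids))
    classes[m$lnc_members] <- "lncRNA"
  }
  if (!allow_overlap && length(modules) > 1) {
    all_members <- unlist(lapply(modules, `[[`, "gene_ids"))
    dup <- all_members[duplicated(all_members)]
    if (length(dup)) {
      stop("gene assigned to more than one module: ", dup[1])
    }
  }
  # a gene may carry at most one effect per age group
  for (grp in AGE_GROUPS) {
    hit <- unlist(lapply(deg_effects, function(e)
      if (grp %in% e$age_groups) e$gene_ids else character(0)))
    dup <- hit[duplicated(hit)]
    if (length(dup)) {
      stop("conflicting DEG effects in ", grp, " for gene: ", dup[1])
    }
  }
  for (e in deg_effects) stopifnot(all(e$gene_ids %in% gene_ids))
  structure(list(n_genes = n_genes, n_per_cell = n_per_cell,
                 modules = modules, deg_effects = deg_effects,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 background_detect_rate = background_detect_rate,
                 stray_flag_rate = stray_flag_rate,
                 classes = classes, gene_ids = gene_ids, seed = seed),
            class = "SyntheticConfig")
}

planted_shift_matrix <- function(config) {
  # genes x age-group log2 shifts applied to sepsis samples
  shift <- matrix(0, config$n_genes, 2,
                  dimnames = list(config$gene_ids, AGE_GROUPS))
  for (e in config$deg_effects) {
    shift[e$gene_ids, e$age_groups] <-
      shift[e$gene_ids, e$age_groups, drop = FALSE] + e$log2fc
  }
  shift
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Emulates the study design: `4 * n_per_cell` two-colour arrays (adult and
#' elderly subjects, sepsis and control), log-normal ratio noise, planted
#' correlated modules, planted fold-changes and planted age-specific
#' (differentially connected) modules.
#'
#' Per gene g and sample s the generator draws
#' `log2 x[g,s] = mu[g] + lambda_m * f[m,s] +
#' shift[g, group(s)] * I(sepsis) + eps`, where `mu` is the per-gene
#' baseline ratio shared by all samples (see `baseline_sd`), and there is
#' one standard-normal factor `f` per module per sample, centred within
#' each design cell so that planted co-expression cannot alias with the
#' sepsis/control contrast. The loading is
#' `lambda^2 = max(0, c/(1-c) * noise_sd^2 - delta_bar^2/4)` where `c` is the
#' module's `latent_cor` and `delta_bar` the members' mean planted shift in
#' the active group: the shared sepsis response already contributes
#' `delta_bar^2/4` covariance over the pooled samples, and the loading makes
#' up the remainder, so the expected pairwise member correlation equals
#' `latent_cor`. For shift-free modules this reduces to
#' `lambda = sqrt(c/(1-c)) * noise_sd`.
#'
#' Values are exported on the linear ratio scale `2^log2x`. Planted genes are
#' always flagged detected; background genes are fully detected with
#' probability `background_detect_rate` and otherwise carry sporadic flags.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (a `GroundTruth` list: `true_deg_flags` per age group,
#'   `true_module_membership`, `true_hub_lncRNAs`,
#'   `true_diffconnected_lncRNAs`, `planted_log2fc`, `module_pathways`).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_per_cell
  G <- config$n_genes
  samples <- data.frame(
    sample_id = c(sprintf("sa%02d", 1:n), sprintf("ca%02d", 1:n),
                  sprintf("se%02d", 1:n), sprintf("ce%02d", 1:n)),
    age_group = rep(c("adult", "adult", "elderly", "elderly"), each = n),
    status = rep(c("sepsis", "control", "sepsis", "control"), each = n),
    stringsAsFactors = FALSE)
  S <- nrow(samples)

  sigma <- matrix(config$noise_sd, G, S,
                  dimnames = list(config$gene_ids, samples$sample_id))
  for (m in config$modules) {
    active_cols <- samples$age_group %in% m$active_groups
    sigma[m$lnc_members, active_cols] <-
      config$noise_sd * m$hub_noise_factor
  }
  log2x <- matrix(rnorm(G * S), G, S) * sigma
  dimnames(log2x) <- list(config$gene_ids, samples$sample_id)
  log2x <- log2x + rnorm(G, 0, config$baseline_sd)  # per-gene baseline

  shift <- planted_shift_matrix(config)
  for (grp in AGE_GROUPS) {
    sep <- which(samples$age_group == grp & samples$status == "sepsis")
    log2x[, sep] <- log2x[, sep] + shift[, grp]
  }

  cell <- interaction(samples$age_group, samples$status, drop = TRUE)
  for (m in config$modules) {
    for (grp in m$active_groups) {
      idx <- which(samples$age_group == grp)
      f <- rnorm(length(idx))
      for (cl in unique(cell[idx])) {
        j <- which(cell[idx] == cl)
        f[j] <- (f[j] - mean(f[j])) * sqrt(length(j) / (length(j) - 1))
      }
      delta_bar <- mean(shift[m$gene_ids, grp])
      lambda2 <- max(0, m$latent_cor / (1 - m$latent_cor) *
                       config$noise_sd^2 - delta_bar^2 / 4)
      log2x[m$gene_ids, idx] <- log2x[m$gene_ids, idx] +
        sqrt(lambda2) * rep(f, each = length(m$gene_ids))
    }
  }

  planted <- unique(c(unlist(lapply(config$modules, `[[`, "gene_ids")),
                      unlist(lapply(config$deg_effects, `[[`, "gene_ids"))))
  flags <- matrix(FALSE, G, S, dimnames = dimnames(log2x))
  flags[planted, ] <- TRUE
  bg <- setdiff(config$gene_ids, planted)
  if (length(bg)) {
    full <- bg[runif(length(bg)) < config$background_detect_rate]
    flags[full, ] <- TRUE
    sparse <- setdiff(bg, full)
    if (length(sparse)) {
      flags[sparse, ] <- matrix(
        rbinom(length(sparse) * S, 1, config$stray_flag_rate) == 1,
        length(sparse), S)
    }
  }

  genes <- data.frame(gene_id = config$gene_ids,
                      class = unname(config$classes),
                      stringsAsFactors = FALSE)
  ds <- expression_dataset(2^log2x, flags, samples, genes)

  module_names <- if (is.null(names(config$modules)) ||
                      any(!nzchar(names(config$modules)))) {
    sprintf("module_%02d", seq_along(config$modules))
  } else names(config$modules)
  membership <- lapply(config$modules, `[[`, "gene_ids")
  names(membership) <- module_names
  both_active <- vapply(config$modules, function(m)
    length(m$active_groups) == 2, TRUE)
  pathways <- lapply(config$modules, function(m)
    setdiff(m$gene_ids, m$lnc_members))
  names(pathways) <- module_names

  truth <- list(
    true_deg_flags = list(
      adult = config$gene_ids[shift[, "adult"] != 0],
      elderly = config$gene_ids[shift[, "elderly"] != 0]),
    true_module_membership = membership,
    true_hub_lncRNAs = unique(unlist(
      lapply(config$modules[both_active], `[[`, "lnc_members"))),
    true_diffconnected_lncRNAs = unique(unlist(
      lapply(config$modules[!both_active], `[[`, "lnc_members"))),
    planted_log2fc = list(adult = shift[, "adult"],
                          elderly = shift[, "elderly"]),
    module_pathways = pathways)
  list(dataset = ds, truth = truth)
}

#' Default synthetic scenario emulating the study conditions
#'
#' Builds the package's reference simulation: 4 design cells of
#' `n_per_cell = 6` subjects, log2 noise sd 0.5, and
#' \itemize{
#'   \item a 50-gene "translation-like" module (3 lncRNA hubs) active in
#'     both age groups whose members are coordinately down-regulated in
#'     sepsis (log2FC -3), emulating the suppressed ribosomal-protein
#'     program; the shared response supplies the full 0.9 target
#'     correlation;
#'   \item a 50-gene "respiration-like" module (3 lncRNA hubs) active only
#'     in adults, up-regulated in adult sepsis (log2FC +3); its lncRNA
#'     hubs additionally carry a weak opposite shift in the elderly
#'     (log2FC -0.75): an inverted expression pattern whose minor-network
#'     fold-change stays close to 1, so it does not wire the lncRNA into
#'     the elderly network;
#'   \item 200 background DEGs in both groups (100 up, 100 down,
#'     |log2FC| = 2, of which 40 are labelled lncRNA), so that roughly
#'     14-16 percent of detected genes are differentially expressed per
#'     group, of the order observed on real sepsis arrays;
#'   \item unplanted background genes with mixed classes, detected at rate
#'     `background_detect_rate` (default 0.55, giving ~1900 detected
#'     genes).
#' }
#' Effect magnitudes were fixed by a design-stage power analysis so planted
#' effects are detectable at alpha = 0.01 with 6 subjects per arm, and match
#' the 2- to 7-fold changes typical of sepsis microarray candidates.
#'
#' @param n_genes Total genes (default 3000).
#' @param n_per_cell Subjects per design cell (default 6).
#' @param noise_sd Log2 noise sd (default 0.5).
#' @param background_detect_rate Detection rate of unplanted genes
#'   (default 0.55).
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
sepsis_study_config <- function(n_genes = 3000, n_per_cell = 6,
                                noise_sd = 0.5,
                                background_detect_rate = 0.55, seed = 1) {
  stopifnot(n_genes >= 800)
  ids <- sprintf("g%05d", seq_len(n_genes))
  m1 <- ids[1:50]; m2 <- ids[51:100]
  bg_up <- ids[101:200]; bg_dn <- ids[201:300]
  m1_lnc <- m1[1:3]; m2_lnc <- m2[1:3]
  modules <- list(
    translation = planted_module(m1, latent_cor = 0.9,
                                 active_groups = c("adult", "elderly"),
                                 lnc_members = m1_lnc),
    respiration = planted_module(m2, latent_cor = 0.9,
                                 active_groups = "adult",
                                 lnc_members = m2_lnc))
  deg_effects <- list(
    deg_effect(m1, -3.0, c("adult", "elderly")),
    deg_effect(m2, +3.0, "adult"),
    deg_effect(m2_lnc, -0.75, "elderly"),
    deg_effect(bg_up, +2.0, c("adult", "elderly")),
    deg_effect(bg_dn, -2.0, c("adult", "elderly")))
  classes <- rep("protein_coding", n_genes)
  names(classes) <- ids
  classes[c(bg_up[1:20], bg_dn[1:20])] <- "lncRNA"
  classes[c(bg_up[21:25], bg_dn[21:25])] <- "pseudogene"
  null_ids <- ids[301:n_genes]
  n_null <- length(null_ids)
  classes[null_ids[seq_len(floor(n_null * 0.22))]] <- "lncRNA"
  classes[null_ids[seq(floor(n_null * 0.22) + 1,
                       floor(n_null * 0.30))]] <- "pseudogene"
  classes[null_ids[seq(floor(n_null * 0.30) + 1,
                       floor(n_null * 0.35))]] <- "poorly_annotated"
  synthetic_config(n_genes, n_per_cell = n_per_cell, modules = modules,
                   deg_effects = deg_effects, noise_sd = noise_sd,
                   background_detect_rate = background_detect_rate,
                   classes = unname(classes), seed = seed)
}

#' Global-null synthetic configuration
#'
#' No planted modules and no planted effects; every gene is pure log-normal
#' noise and fully detected. Used to check type-I error control of the
#' differential-expression tests.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_cell Subjects per design cell (default 6).
#' @param noise_sd Log2 noise sd (default 0.5).
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
global_null_config <- function(n_genes = 2000, n_per_cell = 6,
                               noise_sd = 0.5, seed = 1) {
  synthetic_config(n_genes, n_per_cell = n_per_cell,
                   noise_sd = noise_sd, background_detect_rate = 1,
                   seed = seed)
}

#' Lay out a synthetic gene catalog on a genome
#'
#' Assigns every gene of a dataset an interval on a small synthetic genome,
#' used by the cis-neighbour analysis. Genes are placed sequentially with
#' seeded lengths and intergenic gaps; `pair_up` forces selected lncRNAs to
#' sit immediately next to a chosen protein-coding gene at a given gap, with
#' wide flanks so the partner is unambiguously the nearest protein-coding
#' neighbour.
#'
#' @param genes Gene table (`gene_id`, `class`), e.g. `ds$genes`.
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes to spread genes over.
#' @param pair_up Optional data frame with columns `lnc`, `pc`, `gap` (bp).
#' @return Data frame: `gene_id`, `chrom`, `start`, `end` (0-based,
#'   half-open), `strand`, `class`.
#' @export
generate_gene_catalog <- function(genes, seed = 1, n_chrom = 5,
                                  pair_up = NULL) {
  set.seed(seed)
  ids <- as.character(genes$gene_id)
  ord <- ids
  forced_gap <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(pair_up)) {
    stopifnot(all(c("lnc", "pc", "gap") %in% names(pair_up)),
              all(pair_up$lnc %in% ids), all(pair_up$pc %in% ids))
    for (i in seq_len(nrow(pair_up))) {
      lnc <- pair_up$lnc[i]; pc <- pair_up$pc[i]
      ord <- ord[ord != lnc]
      ord <- append(ord, lnc, after = which(ord == pc))
      forced_gap[lnc] <- pair_up$gap[i]
    }
  }
  n <- length(ord)
  chunk <- ceiling(seq_len(n) / ceiling(n / n_chrom))
  if (!is.null(pair_up)) {
    # keep forced pairs on one chromosome
    chunk[match(pair_up$lnc, ord)] <- chunk[match(pair_up$pc, ord)]
  }
  chrom <- sprintf("chr%d", chunk)
  lens <- sample(500:5000, n, replace = TRUE)
  gaps <- sample(20000:60000, n, replace = TRUE)
  gaps[!is.na(forced_gap[ord])] <- forced_gap[ord][!is.na(forced_gap[ord])]
  start <- numeric(n)
  pos <- 0; last_chr <- chrom[1]
  for (i in seq_len(n)) {
    if (chrom[i] != last_chr) { pos <- 0; last_chr <- chrom[i] }
    pos <- pos + gaps[i]
    start[i] <- pos
    pos <- pos + lens[i]
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  out <- data.frame(gene_id = ord, chrom = chrom, start = start,
                    end = start + lens, strand = strand,
                    class = genes$class[match(ord, ids)],
                    stringsAsFactors = FALSE)
  out[match(ids, out$gene_id), , drop = FALSE]
}
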