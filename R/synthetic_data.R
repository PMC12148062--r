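#' @title Synthetic neurovascular-unit data with ground truth
#' @description Negative-binomial generators for (i) a labeled single-cell
#'   reference with planted marker genes and (ii) ROI mixtures with known
#'   mixing fractions, a genotype-linked microglia abundance shift, planted
#'   genotype differential expression confined to one cellular unit, planted
#'   correlated ligand-receptor pairs, a sex nuisance effect, and negative
#'   probes. Every stochastic element is seed-reproducible and the full ground
#'   truth is returned so downstream stages have recovery tests.
#' @name synthetic_data
NULL

#' Default cellular-unit names of the neurovascular unit preset
#' @export
nvu_units <- function() c("Endothelial", "Astrocyte", "Neuron", "Microglia",
                          "Oligodendrocyte", "OPC")

#' Generate a labeled single-cell reference with planted markers
#'
#' Counts are negative binomial around per-type mean profiles. Each type owns
#' \code{markers_per_type} marker genes whose mean is elevated
#' \code{marker_fold}-fold over all other types, plus a second tier of
#' \code{enriched_per_type} genes elevated \code{enriched_fold}-fold — the
#' cell-type-enriched program beyond the marker panel, which the ROI
#' generator uses as its pool of plantable differential-expression genes.
#' Marker and enriched genes are drawn from the well-expressed range so the
#' elevation is recoverable from finite counts. Two designated genes are
#' named after the opioid ligand-receptor pair the ROI generator can plant:
#' the first Endothelial marker becomes \code{Pdyn} — its expression outside
#' the endothelium is suppressed by \code{ligand_restriction}, emulating a
#' cell-restricted neuropeptide — and one broadly expressed non-marker gene
#' becomes \code{Oprk1}.
#'
#' @param n_types number of cell types (>= 2).
#' @param cells_per_type cells simulated per type.
#' @param n_genes total genes.
#' @param markers_per_type marker genes owned by each type;
#'   \code{(markers_per_type + enriched_per_type) * n_types} must not exceed
#'   \code{n_genes}.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param n_animals donor animals, assigned round-robin.
#' @param marker_fold mean fold-elevation of a marker in its own type.
#' @param enriched_per_type,enriched_fold size and fold-elevation of the
#'   enriched (non-marker) tier per type.
#' @param ligand_restriction multiplier applied to the ligand gene's mean
#'   outside its source type (default 0: exclusive expression, as for a
#'   tightly cell-restricted neuropeptide).
#' @param type_names optional type labels (default: the six NVU units when
#'   \code{n_types == 6}, otherwise \code{Type1..n}).
#' @return list with \code{sc} (\code{\link{nvu_sc}}), \code{signatures}
#'   (marker gene sets, GMT-compatible), \code{enriched} (per-type enriched
#'   gene lists), and \code{type_means} (genes x types matrix of generating
#'   negative-binomial means).
#' @export
generate_reference_scrna <- function(n_types = 6, cells_per_type = 200,
                                     n_genes = 2000, markers_per_type = 30,
                                     seed = 1, n_animals = 8,
                                     marker_fold = 6,
                                     enriched_per_type = 60,
                                     enriched_fold = 3,
                                     ligand_restriction = 0,
                                     type_names = NULL) {
  if (n_types < 2) stop("n_types must be >= 2")
  if ((markers_per_type + enriched_per_type) * n_types > n_genes)
    stop("infeasible marker allocation: ",
         "(markers_per_type + enriched_per_type) * n_types > n_genes")
  if (is.null(type_names))
    type_names <- if (n_types == 6) nvu_units() else paste0("Type", seq_len(n_types))
  stopifnot(length(type_names) == n_types)

  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    base_mu <- rlnorm(n_genes, meanlog = log(3), sdlog = 1)
    marker_idx <- matrix(seq_len(markers_per_type * n_types),
                         nrow = markers_per_type)
    enr_idx <- matrix(markers_per_type * n_types +
                        seq_len(enriched_per_type * n_types),
                      nrow = max(enriched_per_type, 1))
    # markers and enriched genes live in the well-expressed range
    base_mu[as.vector(marker_idx)] <- rlnorm(markers_per_type * n_types,
                                             meanlog = log(5), sdlog = 0.5)
    if (enriched_per_type > 0)
      base_mu[as.vector(enr_idx)] <- rlnorm(enriched_per_type * n_types,
                                            meanlog = log(5), sdlog = 0.5)
    wobble <- matrix(exp(rnorm(n_genes * n_types, sd = 0.1)),
                     n_genes, n_types)
    mu <- base_mu * wobble
    for (t in seq_len(n_types)) {
      mu[marker_idx[, t], t] <- mu[marker_idx[, t], t] * marker_fold
      if (enriched_per_type > 0)
        mu[enr_idx[, t], t] <- mu[enr_idx[, t], t] * enriched_fold
    }
    dimnames(mu) <- list(genes, type_names)

    # cell-restricted ligand: first Endothelial marker, suppressed elsewhere
    if ("Endothelial" %in% type_names) {
      e <- match("Endothelial", type_names)
      lig <- marker_idx[1, e]
      mu[lig, -e] <- mu[lig, -e] * ligand_restriction
    }

    phi <- 10^runif(n_genes, -1, 0)  # var = mu + phi * mu^2
    n_cells <- cells_per_type * n_types
    counts <- matrix(0L, n_cells, n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    cluster <- rep(type_names, each = cells_per_type)
    for (i in seq_len(n_cells)) {
      lib <- rlnorm(1, 0, 0.3)
      counts[i, ] <- rnbinom(n_genes, mu = mu[, cluster[i]] * lib,
                             size = 1 / phi)
    }

    sigs <- lapply(seq_len(n_types), function(t) genes[marker_idx[, t]])
    names(sigs) <- type_names
    enriched <- if (enriched_per_type > 0)
      setNames(lapply(seq_len(n_types), function(t) genes[enr_idx[, t]]),
               type_names) else NULL

    # name the plantable ligand-receptor pair after the opioid genes
    if ("Endothelial" %in% type_names) {
      lig_old <- genes[marker_idx[1, match("Endothelial", type_names)]]
      structured <- c(as.vector(marker_idx), as.vector(enr_idx))
      nonstruct <- setdiff(seq_len(n_genes), structured)
      rec_old <- genes[nonstruct[which.max(base_mu[nonstruct])]]
      ren <- c(Pdyn = lig_old, Oprk1 = rec_old)
      for (new in names(ren)) {
        old <- ren[[new]]
        genes[genes == old] <- new
        sigs <- lapply(sigs, function(s) { s[s == old] <- new; s })
      }
      colnames(counts) <- genes
      rownames(mu) <- genes
    }

    list(sc = nvu_sc(counts, cluster = cluster,
                     animal = paste0("a", (seq_len(n_cells) %% n_animals) + 1)),
         signatures = list(name = "synthetic_markers", sets = sigs),
         enriched = enriched,
         type_means = mu)
  })
}

#' Configuration of the ROI mixture generator
#'
#' Defaults encode the study conditions the pipeline is tested under: median
#' unit prevalences dominated by endothelium / neurons / astrocytes, a +0.05
#' additive APP+ microglia fraction shift, 2-fold genotype effects confined to
#' the endothelial contribution, one planted opioid ligand-receptor pair
#' (\code{Pdyn} from the endothelial vasculature to the four NVU units,
#' including itself), a 1.1x library-size sex effect, and 20 low-mean negative
#' probes.
#'
#' @param base_props named median unit proportions (summing to 1).
#' @param dirichlet_conc total Dirichlet concentration of the fraction draws.
#' @param gradient named loading vector of the neurovascular enrichment axis:
#'   each segment draws a latent position t ~ N(0, gradient_sd) and unit u's
#'   weight is multiplied by exp(gradient[u] * t) before renormalization. The
#'   default (+1 endothelial, -1 neuron) reproduces the strong negative
#'   neuron-vasculature prevalence correlation observed in endothelially
#'   targeted ROIs (Spearman near -0.8), which a plain Dirichlet cannot reach.
#' @param gradient_sd SD of the latent axis position (0 disables it).
#' @param gradient_clamp the axis position is clamped to +/- this value:
#'   ROIs are drawn on vascular staining, so the cohort cannot contain
#'   segments essentially devoid of endothelium (the clamp bounds the
#'   minimum endothelial fraction near 4 percent).
#' @param microglia_shift additive APP+ fraction shift applied to
#'   \code{shift_unit} (other units rescaled to keep the simplex).
#' @param shift_unit unit receiving the genotype abundance shift.
#' @param de data.frame(unit, gene, lfc) of planted genotype log2 fold changes,
#'   applied multiplicatively inside that unit's contribution for APP+
#'   segments; \code{NULL} selects \code{n_de_up}/\code{n_de_dn} non-marker
#'   genes in \code{de_unit} at \code{|lfc| = de_lfc}.
#' @param de_unit,n_de_up,n_de_dn,de_lfc defaults for the planted DE block.
#' @param lr data.frame(ligand, receptor, source, target, rho) of planted
#'   ligand-receptor correlations (shared per-ROI log-normal latent factor).
#' @param lr_sd log-scale SD of the shared latent factor.
#' @param lr_lfc genotype log2 fold change planted on the ligand (in its
#'   source unit) and receptor (in each target unit); the reported pairs are
#'   robustly up-regulated, so the default exceeds the generic DE effect.
#' @param n_neg,neg_mean,neg_phi negative-probe count, NB mean and dispersion.
#' @param lib_size,lib_sd expected segment library size and its log-normal SD.
#' @param sex_mult library-size multiplier applied to male mice.
#' @param noise if \code{FALSE}, segments are the exact mixtures of unit mean
#'   profiles (no sampling; the noiseless limit).
#' @return a config list consumed by \code{\link{generate_roi_dataset}}.
#' @export
roi_config <- function(base_props = c(Endothelial = 0.32, Neuron = 0.28,
                                      Astrocyte = 0.25, Microglia = 0.05,
                                      Oligodendrocyte = 0.05, OPC = 0.05),
                       dirichlet_conc = 15,
                       gradient = c(Endothelial = 1, Neuron = -1),
                       gradient_sd = 0.7, gradient_clamp = 1,
                       microglia_shift = 0.05, shift_unit = "Microglia",
                       de = NULL, de_unit = "Endothelial",
                       n_de_up = 30, n_de_dn = 30, de_lfc = 1,
                       lr = data.frame(
                         ligand = "Pdyn", receptor = "Oprk1",
                         source = "Endothelial",
                         target = c("Endothelial", "Astrocyte", "Neuron",
                                    "Microglia"),
                         rho = 0.6, stringsAsFactors = FALSE),
                       lr_sd = 0.8, lr_lfc = 2,
                       n_neg = 20, neg_mean = 8, neg_phi = 0.5,
                       lib_size = 2e5, lib_sd = 0.2, sex_mult = 1.1,
                       noise = TRUE) {
  base_props <- base_props / sum(base_props)
  list(base_props = base_props, dirichlet_conc = dirichlet_conc,
       gradient = gradient, gradient_sd = gradient_sd,
       gradient_clamp = gradient_clamp,
       microglia_shift = microglia_shift, shift_unit = shift_unit,
       de = de, de_unit = de_unit, n_de_up = n_de_up, n_de_dn = n_de_dn,
       de_lfc = de_lfc, lr = lr, lr_sd = lr_sd, lr_lfc = lr_lfc,
       n_neg = n_neg,
       neg_mean = neg_mean, neg_phi = neg_phi, lib_size = lib_size,
       lib_sd = lib_sd, sex_mult = sex_mult, noise = noise)
}

#' Null configuration: no planted effects
#' @param ... overrides forwarded to \code{\link{roi_config}}.
#' @return a config with no abundance shift, no DE, no LR planting.
#' @export
roi_config_null <- function(...) {
  roi_config(microglia_shift = 0, de = data.frame(unit = character(),
                                                  gene = character(),
                                                  lfc = numeric()),
             lr = NULL, ...)
}

# Dirichlet draw via gamma representation
.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# per-segment enrichment axis: w_u *= exp(gradient_u * t), renormalized
.apply_gradient <- function(fr, gradient, t_pos, clamp = Inf) {
  if (is.null(gradient) || !length(gradient)) return(fr)
  t_pos <- pmax(pmin(t_pos, clamp), -clamp)
  load <- setNames(rep(0, ncol(fr)), colnames(fr))
  load[intersect(names(gradient), colnames(fr))] <-
    gradient[intersect(names(gradient), colnames(fr))]
  fr <- fr * exp(outer(t_pos, load))
  fr / rowSums(fr)
}

# additive shift on one simplex coordinate, others rescaled
.apply_shift <- function(fr, unit, delta) {
  if (delta == 0 || !(unit %in% colnames(fr))) return(fr)
  m <- fr[, unit]
  m2 <- pmin(m + delta, 0.999)
  scale <- (1 - m2) / (1 - m)
  fr <- fr * scale
  fr[, unit] <- m2
  fr
}

#' Sample a ground-truth fraction table without generating counts
#'
#' Used for calibration and power studies of the abundance test: Dirichlet
#' fraction rows for an APP- and an APP+ arm, with the configured microglia
#' shift applied to the APP+ arm.
#'
#' @param n_neg,n_pos segments per genotype arm.
#' @param config a \code{\link{roi_config}}.
#' @param seed integer seed.
#' @return list with \code{fractions} (rows on the simplex) and
#'   \code{genotype}.
#' @export
simulate_fraction_table <- function(n_neg, n_pos, config = roi_config(),
                                    seed = 1) {
  withr::with_seed(seed, {
    alpha <- config$dirichlet_conc * config$base_props
    fr <- .rdirichlet(n_neg + n_pos, alpha)
    colnames(fr) <- names(config$base_props)
    fr <- .apply_gradient(fr, config$gradient,
                          rnorm(n_neg + n_pos, 0, config$gradient_sd),
                          config$gradient_clamp %||% Inf)
    genotype <- rep(c("APP-", "APP+"), c(n_neg, n_pos))
    pos <- genotype == "APP+"
    fr[pos, ] <- .apply_shift(fr[pos, , drop = FALSE], config$shift_unit,
                              config$microglia_shift)
    list(fractions = fr, genotype = genotype)
  })
}

#' Generate an ROI mixture dataset with full ground truth
#'
#' Each segment's expected expression is the fraction-weighted mixture of the
#' reference's per-unit mean profiles (library-normalized to counts per 10k).
#' Planted genotype effects multiply the designated unit's contribution by
#' \code{2^lfc} for APP+ segments; planted ligand-receptor correlations scale
#' the ligand gene in its source unit and the receptor gene in each target
#' unit by one shared per-segment log-normal factor; the mixture is then
#' scaled to the segment library size and sampled negative-binomially.
#' Negative-probe rows are iid low-mean negative binomial.
#'
#' @param ref output of \code{\link{generate_reference_scrna}} (or an
#'   \code{\link{nvu_sc}}; unit profiles are then the per-cluster means).
#' @param n_mice number of mice, assigned round-robin to the four
#'   genotype-by-sex groups (12 gives the balanced 3/3/3/3 design).
#' @param rois_per_mouse segments collected per mouse.
#' @param seed integer seed.
#' @param config a \code{\link{roi_config}}.
#' @return list with \code{expr} (\code{\link{nvu_expr}}, raw counts including
#'   negative probes), \code{annot} (segment annotation), and \code{truth}
#'   (fractions, planted DE table, planted LR table, microglia shift, latent
#'   factors).
#' @export
generate_roi_dataset <- function(ref, n_mice = 12, rois_per_mouse = 11,
                                 seed = 1, config = roi_config()) {
  sc <- if (inherits(ref, "nvu_sc")) ref else ref$sc
  marker_sets <- if (inherits(ref, "nvu_sc")) NULL else ref$signatures$sets
  enriched_sets <- if (inherits(ref, "nvu_sc")) NULL else ref$enriched

  # per-unit mean profile, depth-normalized (counts per 10k)
  cp10k <- sc$counts / pmax(rowSums(sc$counts), 1) * 1e4
  units <- sort(unique(sc$cluster))
  M <- vapply(units, function(u) colMeans(cp10k[sc$cluster == u, , drop = FALSE]),
              numeric(ncol(sc$counts)))
  genes <- colnames(sc$counts)

  cfg <- config
  if (!all(names(cfg$base_props) %in% units))
    stop("config base_props name units absent from the reference: ",
         paste(setdiff(names(cfg$base_props), units), collapse = ", "))
  M <- M[, names(cfg$base_props), drop = FALSE]
  units <- colnames(M)

  # default planted DE block: the de_unit's enriched (non-marker) program,
  # topped up with well-expressed unstructured genes if needed
  if (is.null(cfg$de)) {
    excluded <- unique(c(unlist(marker_sets), cfg$lr$ligand, cfg$lr$receptor))
    pool <- setdiff(enriched_sets[[cfg$de_unit]], excluded)
    extra <- setdiff(genes, c(excluded, pool, unlist(enriched_sets)))
    extra <- extra[order(M[match(extra, genes), cfg$de_unit],
                         decreasing = TRUE)]
    pool <- c(pool, extra)
    picked <- pool[seq_len(cfg$n_de_up + cfg$n_de_dn)]
    cfg$de <- data.frame(unit = cfg$de_unit, gene = picked,
                         lfc = rep(c(cfg$de_lfc, -cfg$de_lfc),
                                   c(cfg$n_de_up, cfg$n_de_dn)),
                         stringsAsFactors = FALSE)
  }
  # LR genes must also be up-regulated where they act
  if (!is.null(cfg$lr) && nrow(cfg$lr)) {
    lr_de <- unique(rbind(
      data.frame(unit = cfg$lr$source, gene = cfg$lr$ligand, lfc = cfg$lr_lfc,
                 stringsAsFactors = FALSE),
      data.frame(unit = cfg$lr$target, gene = cfg$lr$receptor,
                 lfc = cfg$lr_lfc, stringsAsFactors = FALSE)))
    cfg$de <- unique(rbind(cfg$de, lr_de))
  }
  if (nrow(cfg$de) && !all(cfg$de$gene %in% genes))
    stop("planted DE gene(s) not in reference gene list: ",
         paste(setdiff(cfg$de$gene, genes), collapse = ", "))

  n_seg <- n_mice * rois_per_mouse
  group <- data.frame(genotype = rep(c("APP-", "APP-", "APP+", "APP+"),
                                     length.out = n_mice),
                      sex = rep(c("F", "M"), length.out = n_mice))
  mouse_id <- sprintf("m%02d", seq_len(n_mice))

  withr::with_seed(seed, {
    annot <- data.frame(
      segment_id = sprintf("S%03d", seq_len(n_seg)),
      roi_id = sprintf("R%03d", seq_len(n_seg)),
      mouse_id = rep(mouse_id, each = rois_per_mouse),
      genotype = rep(group$genotype, each = rois_per_mouse),
      sex = rep(group$sex, each = rois_per_mouse),
      region = rep_len(c("cortex", "hippocampus"), n_seg),
      stringsAsFactors = FALSE)
    annot$nuclei <- round(pmax(rnorm(n_seg, 100, 10), 50))

    alpha <- cfg$dirichlet_conc * cfg$base_props
    fr <- .rdirichlet(n_seg, alpha)
    colnames(fr) <- units
    rownames(fr) <- annot$segment_id
    fr <- .apply_gradient(fr, cfg$gradient, rnorm(n_seg, 0, cfg$gradient_sd),
                          cfg$gradient_clamp %||% Inf)
    pos <- annot$genotype == "APP+"
    fr[pos, ] <- .apply_shift(fr[pos, , drop = FALSE], cfg$shift_unit,
                              cfg$microglia_shift)

    # shared per-segment latent factor, one per planted ligand-receptor pair
    latent <- NULL
    if (!is.null(cfg$lr) && nrow(cfg$lr)) {
      pairs <- unique(cfg$lr[, c("ligand", "receptor")])
      latent <- matrix(exp(rnorm(n_seg * nrow(pairs), sd = cfg$lr_sd)),
                       n_seg, nrow(pairs))
      colnames(latent) <- paste(pairs$ligand, pairs$receptor, sep = "|")
    }

    phi <- 10^runif(length(genes), -1, 0)
    counts <- matrix(0, length(genes), n_seg,
                     dimnames = list(genes, annot$segment_id))
    for (i in seq_len(n_seg)) {
      mult <- matrix(1, length(genes), length(units),
                     dimnames = list(genes, units))
      if (pos[i] && nrow(cfg$de))
        mult[cbind(match(cfg$de$gene, genes), match(cfg$de$unit, units))] <-
          2^cfg$de$lfc
      if (!is.null(latent)) {
        keys <- paste(cfg$lr$ligand, cfg$lr$receptor, sep = "|")
        # the ligand is scaled once per (ligand, source, pair), even when
        # the pair table lists one row per target unit
        lig_once <- !duplicated(paste(cfg$lr$ligand, cfg$lr$source, keys))
        for (p in seq_len(nrow(cfg$lr))) {
          f <- latent[i, keys[p]]
          if (lig_once[p])
            mult[cfg$lr$ligand[p], cfg$lr$source[p]] <-
              mult[cfg$lr$ligand[p], cfg$lr$source[p]] * f
          mult[cfg$lr$receptor[p], cfg$lr$target[p]] <-
            mult[cfg$lr$receptor[p], cfg$lr$target[p]] * f
        }
      }
      expected <- as.vector((M * mult) %*% fr[i, ])
      if (!cfg$noise) {
        counts[, i] <- expected
      } else {
        lib <- cfg$lib_size *
          (if (annot$sex[i] == "M") cfg$sex_mult else 1) *
          rlnorm(1, 0, cfg$lib_sd)
        mu_i <- expected / sum(expected) * lib
        counts[, i] <- rnbinom(length(genes), mu = mu_i, size = 1 / phi)
      }
    }

    neg <- matrix(if (cfg$noise)
      rnbinom(cfg$n_neg * n_seg, mu = cfg$neg_mean, size = 1 / cfg$neg_phi)
      else cfg$neg_mean,
      cfg$n_neg, n_seg,
      dimnames = list(sprintf("NegProbe-%02d", seq_len(cfg$n_neg)),
                      annot$segment_id))

    all_counts <- rbind(counts, neg)
    expr <- nvu_expr(all_counts,
                     negative = c(rep(FALSE, length(genes)),
                                  rep(TRUE, cfg$n_neg)),
                     stage = "raw")
    truth <- list(fractions = fr, de = cfg$de, lr = cfg$lr,
                  microglia_shift = cfg$microglia_shift,
                  shift_unit = cfg$shift_unit, latent = latent)
    list(expr = expr, annot = annot, truth = truth)
  })
}
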