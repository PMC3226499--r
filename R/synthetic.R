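#' Configuration for the synthetic HTS study generator
#'
#' Defaults emulate a phase-I-like screening campaign: 309 chemicals by 120
#' assays, of which 23 assays span the six vascular target features; about
#' 40% of chemicals are planted vascular actives (each hitting its
#' mechanism-feature pair plus 1-4 further features), hit potencies are
#' log10-uniform over 0.1-50 uM (the span of curated reference AC50s), and
#' every remaining cell is a false hit at rate 0.02. Endpoint generation
#' links the two planted mechanism groups to species-specific developmental
#' outcomes: plasminogen-activating-system (PAS) actives produce rabbit
#' fetal/maternal-loss records with probability `p_species_a`, chemokine
#' actives produce rat skeletal records with probability `p_species_b`,
#' with record species flipped at `label_noise`.
#'
#' @param n_chemicals,n_assays Matrix dimensions; `n_assays` must cover the
#'   23-assay vascular panel.
#' @param active_fraction Fraction of chemicals planted as vascular actives.
#' @param potency_range Hit potency bounds in uM (log10-uniform sampling).
#' @param background_rate False-hit probability per inactive cell.
#' @param assay_hit_prob Probability that an active chemical hits each
#'   individual assay of one of its active features (at least one is
#'   guaranteed).
#' @param p_species_a,p_species_b Probability that a PAS-linked (resp.
#'   chemokine-linked) active receives endpoint records in its species.
#' @param label_noise Probability that a record's species is flipped.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_chemicals = 309, n_assays = 120,
                             active_fraction = 0.4,
                             potency_range = c(0.1, 50),
                             background_rate = 0.02,
                             assay_hit_prob = 0.8,
                             p_species_a = 0.85, p_species_b = 0.8,
                             label_noise = 0.05, seed = 1) {
  probs <- c(active_fraction, background_rate, assay_hit_prob,
             p_species_a, p_species_b, label_noise)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(potency_range <= 0) || any(potency_range >= inactive_sentinel()) ||
      potency_range[1] > potency_range[2])
    stop("potency_range must be increasing within (0, 1e6)", call. = FALSE)
  structure(list(n_chemicals = n_chemicals, n_assays = n_assays,
                 active_fraction = active_fraction,
                 potency_range = potency_range,
                 background_rate = background_rate,
                 assay_hit_prob = assay_hit_prob,
                 p_species_a = p_species_a, p_species_b = p_species_b,
                 label_noise = label_noise, seed = seed),
            class = "generator_config")
}

# The synthetic vascular panel: 23 assays over the six target features,
# with the gene symbol each feature reads out.
vascular_panel <- function() {
  data.frame(
    target_feature = rep(c("VEGFR2_down", "TIE2_inhib", "CCL2_down",
                           "PAI1_updown", "CXCL10_up", "uPAR_updown"),
                         times = c(4, 4, 4, 4, 4, 3)),
    gene_symbol = rep(c("KDR", "TEK", "CCL2", "SERPINE1", "CXCL10", "PLAUR"),
                      times = c(4, 4, 4, 4, 4, 3)),
    stringsAsFactors = FALSE)
}

# Mechanism group -> the target features it perturbs.
mechanism_features <- function() {
  list(PAS = c("PAI1_updown", "uPAR_updown"),
       chemokine = c("CCL2_down", "CXCL10_up"))
}

#' Generate a synthetic HTS potency matrix with planted vascular actives
#'
#' Planted actives hit both features of their mechanism group (PAS or
#' chemokine) plus 1-4 of the remaining four vascular features, so every
#' active spans at least 3 of the 6 features; each assay of an active
#' feature is hit with probability `assay_hit_prob` (at least one
#' guaranteed). All other cells are false hits at `background_rate`.
#'
#' @param cfg A [generator_config()].
#' @return List with `matrix` (a [potency_matrix()]), `annotations`
#'   (assay annotation data.frame), `active` (planted active chemical ids),
#'   `mechanism` (named vector: `"PAS"` or `"chemokine"` per active) and
#'   `config`.
#' @export
generate_hts <- function(cfg = generator_config()) {
  panel <- vascular_panel()
  if (cfg$n_assays < nrow(panel))
    stop("n_assays must be at least ", nrow(panel),
         " to cover the vascular panel", call. = FALSE)
  n_bg <- cfg$n_assays - nrow(panel)
  suffix <- stats::ave(seq_len(nrow(panel)), panel$target_feature,
                       FUN = seq_along)
  vascular_ids <- sprintf("%s_%s_%d",
                          ifelse(panel$target_feature == "TIE2_inhib",
                                 "NVS", "BSK"),
                          panel$target_feature, suffix)
  bg_ids <- sprintf("BG_%04d", seq_len(n_bg))
  chems <- sprintf("chem%04d", seq_len(cfg$n_chemicals))
  lo <- log10(cfg$potency_range[1]); hi <- log10(cfg$potency_range[2])
  with_seed(cfg$seed, {
    bg_genes <- if (n_bg > 0)
      sample(sprintf("G%03d", 1:40), n_bg, replace = TRUE) else character(0)
    ann <- data.frame(
      assay_id = c(vascular_ids, bg_ids),
      platform = c(ifelse(panel$target_feature == "TIE2_inhib",
                          "NVS", "BSK"), rep("BG", n_bg)),
      cell_system = c(ifelse(panel$target_feature == "TIE2_inhib",
                             "cell-free", "BSK:mixed"),
                      rep("CLM:HepG2", n_bg)),
      gene_symbol = c(panel$gene_symbol, bg_genes),
      target_feature = c(panel$target_feature, rep("", n_bg)),
      direction = c(sub("^.*_(down|up|updown|inhib)$", "\\1",
                        panel$target_feature), rep("na", n_bg)),
      measure = c(ifelse(panel$target_feature == "TIE2_inhib",
                         "AC50", "LEC"), rep("AC50", n_bg)),
      stringsAsFactors = FALSE)
    ann$direction[ann$direction == "inhib"] <- "down"
    n_active <- round(cfg$active_fraction * cfg$n_chemicals)
    active <- sort(sample(chems, n_active))
    mech <- setNames(rep(c("PAS", "chemokine"), length.out = n_active),
                     active)
    vals <- matrix(inactive_sentinel(), cfg$n_chemicals, cfg$n_assays,
                   dimnames = list(chems, c(vascular_ids, bg_ids)))
    bg_mask <- matrix(runif(length(vals)) < cfg$background_rate,
                      nrow(vals), ncol(vals))
    vals[bg_mask] <- 10^runif(sum(bg_mask), lo, hi)
    mf <- mechanism_features()
    all_feats <- unique(panel$target_feature)
    for (ch in active) {
      own <- mf[[mech[ch]]]
      extras <- sample(setdiff(all_feats, own), sample(1:4, 1))
      for (tg in c(own, extras)) {
        cols <- which(panel$target_feature == tg)
        hit <- runif(length(cols)) < cfg$assay_hit_prob
        if (!any(hit)) hit[sample(length(cols), 1)] <- TRUE
        vals[ch, cols[hit]] <- 10^runif(sum(hit), lo, hi)
      }
    }
  })
  list(matrix = potency_matrix(vals, provenance = "synthetic"),
       annotations = ann, active = active, mechanism = mech, config = cfg)
}

#' Generate synthetic prenatal endpoint records for planted actives
#'
#' PAS-linked actives receive rabbit records drawn from
#' `"maternal pregnancy loss"` / `"embryo fetal loss"` with probability
#' `p_species_a`; chemokine-linked actives receive rat records from
#' `"skeletal: axial"` / `"skeletal: appendicular"` with `p_species_b`.
#' Each emitted record's species is flipped with probability `label_noise`.
#' Ground-truth species labels are the mechanism mapping before noise.
#'
#' @param cfg A [generator_config()].
#' @param active Planted active chemical ids.
#' @param mechanism Named vector (`"PAS"`/`"chemokine"`) over `active`.
#' @param seed Seed for this stage (default `cfg$seed`).
#' @return List with `records` (endpoint data.frame, possibly empty) and
#'   `truth` (list `rabbit_only`, `rat_only`).
#' @export
generate_endpoints <- function(cfg, active, mechanism, seed = cfg$seed) {
  cat_of <- list(PAS = c("maternal pregnancy loss", "embryo fetal loss"),
                 chemokine = c("skeletal: axial", "skeletal: appendicular"))
  sp_of <- c(PAS = "rabbit", chemokine = "rat")
  p_of <- c(PAS = cfg$p_species_a, chemokine = cfg$p_species_b)
  rows <- list()
  with_seed(seed, {
    for (ch in active) {
      mech <- mechanism[[ch]]
      if (runif(1) >= p_of[[mech]]) next
      cats <- sample(cat_of[[mech]], sample(1:2, 1))
      for (cc in cats) {
        sp <- sp_of[[mech]]
        if (runif(1) < cfg$label_noise)
          sp <- setdiff(c("rat", "rabbit"), sp)
        rows[[length(rows) + 1]] <- data.frame(
          chemical = ch, species = sp, category = cc,
          lel = round(10^runif(1, 0, 3), 2), stringsAsFactors = FALSE)
      }
    }
  })
  records <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chemical = character(0), species = character(0),
               category = character(0), lel = numeric(0),
               stringsAsFactors = FALSE)
  list(records = records,
       truth = list(rabbit_only = names(mechanism)[mechanism == "PAS"],
                    rat_only = names(mechanism)[mechanism == "chemokine"]))
}

#' Generate synthetic pathway gene sets over the annotation gene pool
#'
#' Always includes a PAS pathway (SERPINE1, PLAUR plus sampled background
#' genes) and a chemokine pathway (CCL2, CXCL10 plus sampled genes), then
#' fills up with random gene sets, with source tags drawn from GO/KEGG/IPA.
#'
#' @param annotations Annotation data.frame supplying the gene pool.
#' @param n_pathways Total number of pathways (>= 2).
#' @param size Range of random pathway sizes.
#' @param seed Integer seed.
#' @return A [pathway_set()].
#' @export
generate_pathways <- function(annotations, n_pathways = 8, size = c(5, 15),
                              seed = 1) {
  if (n_pathways < 2) stop("n_pathways must be >= 2", call. = FALSE)
  pool <- unique(annotations$gene_symbol)
  pool <- pool[nzchar(pool)]
  with_seed(seed, {
    genes <- list(
      unique(c("SERPINE1", "PLAUR",
               sample(pool, min(6, length(pool))))),
      unique(c("CCL2", "CXCL10",
               sample(pool, min(6, length(pool))))))
    for (i in seq_len(n_pathways - 2)) {
      genes[[i + 2]] <- sample(pool, min(sample(size[1]:size[2], 1),
                                         length(pool)))
    }
    src <- sample(c("GO:Process", "KEGG", "IPA"), n_pathways, replace = TRUE)
  })
  pathway_set(ids = c("PAS_proteolysis", "chemokine_signaling",
                      sprintf("pathway_%02d", seq_len(n_pathways - 2))),
              genes = genes,
              source = c("GO:Process", "KEGG", src[-(1:2)])[1:n_pathways])
}

#' Write a full synthetic study to disk
#'
#' Generates the potency matrix, annotations, pathway gene sets and
#' endpoint table under one configuration and writes them as plain-text
#' files plus a JSON ground-truth manifest.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of files written.
#' @export
simulate_study <- function(cfg = generator_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hts <- generate_hts(cfg)
  ep <- generate_endpoints(cfg, hts$active, hts$mechanism)
  pw <- generate_pathways(hts$annotations, seed = cfg$seed)
  files <- list(matrix = file.path(out_dir, "potency_matrix.csv"),
                annotations = file.path(out_dir, "annotations.csv"),
                pathways = file.path(out_dir, "pathways.gmt"),
                endpoints = file.path(out_dir, "endpoints.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_potency_matrix(hts$matrix, files$matrix)
  write.csv(hts$annotations, files$annotations, row.names = FALSE)
  write_gmt(pw, files$pathways)
  write.csv(ep$records, files$endpoints, row.names = FALSE, na = "")
  jsonlite::write_json(list(config = unclass(cfg), active = hts$active,
                            mechanism = as.list(hts$mechanism),
                            truth = ep$truth),
                       files$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
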