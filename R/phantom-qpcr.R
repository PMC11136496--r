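## qRT-PCR Ct-table simulator: technical triplicates within biological
## replicates for control/treated conditions, with known fold changes
## (encoded as Ct shifts of -log2(fold) in the treated condition) and
## optional injected gross outliers for exercising the Dixon gate.

#' Configuration for the Ct-table simulator
#'
#' @param genes target gene names.
#' @param fold_changes named numeric: true treated/control fold change per
#'   gene (recycled if unnamed scalar).
#' @param reference_gene endogenous control name.
#' @param n_bio biological replicates per condition.
#' @param base_ct_gene,base_ct_ref baseline Ct of targets and reference.
#' @param tech_sd technical (within-triplicate) Ct SD, cycles.
#' @param bio_sd biological (between-replicate) Ct SD, cycles.
#' @param n_outliers number of triplicates (chosen at random among
#'   sample x gene combinations) that receive one gross outlier.
#' @param outlier_shift Ct shift of the injected outlier, cycles.
#' @param seed RNG seed.
#' @return List of class `ct_sim_config`.
#' @export
ct_sim_config <- function(genes = c("myb", "runx1"), fold_changes = 2,
                          reference_gene = "ef1a", n_bio = 3L,
                          base_ct_gene = 20, base_ct_ref = 15,
                          tech_sd = 0.05, bio_sd = 0, n_outliers = 0L,
                          outlier_shift = 5, seed = 1L) {
  stopifnot_scalar_pos(tech_sd, "tech_sd", strict = FALSE)
  stopifnot_scalar_pos(bio_sd, "bio_sd", strict = FALSE)
  if (any(fold_changes <= 0)) eht_stop("eht_config_error", "fold changes must be > 0")
  fold <- rep_len(fold_changes, length(genes))
  if (!is.null(names(fold_changes)) && all(genes %in% names(fold_changes))) {
    fold <- unname(fold_changes[genes])
  }
  cfg <- as.list(environment())
  cfg$fold <- fold
  class(cfg) <- "ct_sim_config"
  cfg
}

#' Simulate a Ct table with known fold changes
#'
#' @param cfg a [ct_sim_config()].
#' @return List: `table` (sample, condition, gene, replicate, ct), `truth`
#'   data.frame (gene, fold_true) and `outliers` (sample, gene, injected
#'   value) for the gated triplicates.
#' @export
make_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  with_seed(cfg$seed, {
    conds <- c("control", "treated")
    rows <- list()
    for (cond in conds) for (b in seq_len(cfg$n_bio)) {
      samp <- sprintf("%s_%d", cond, b)
      bio_shift <- if (cfg$bio_sd > 0) stats::rnorm(1, 0, cfg$bio_sd) else 0
      ## reference gene
      ct_ref <- cfg$base_ct_ref + bio_shift +
        stats::rnorm(3, 0, cfg$tech_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samp, condition = cond, gene = cfg$reference_gene,
        replicate = 1:3, ct = ct_ref)
      for (gi in seq_along(cfg$genes)) {
        mu <- cfg$base_ct_gene + bio_shift -
          if (cond == "treated") log2(cfg$fold[gi]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samp, condition = cond, gene = cfg$genes[gi],
          replicate = 1:3, ct = mu + stats::rnorm(3, 0, cfg$tech_sd))
      }
    }
    tab <- do.call(rbind, rows)
    outliers <- data.frame(sample = character(0), gene = character(0),
                           value = numeric(0))
    if (cfg$n_outliers > 0) {
      key <- unique(tab[tab$gene != cfg$reference_gene, c("sample", "gene")])
      pick <- key[sample(nrow(key), min(cfg$n_outliers, nrow(key))), , drop = FALSE]
      for (k in seq_len(nrow(pick))) {
        idx <- which(tab$sample == pick$sample[k] & tab$gene == pick$gene[k])
        hit <- idx[sample(3, 1)]
        tab$ct[hit] <- tab$ct[hit] + cfg$outlier_shift
        outliers <- rbind(outliers, data.frame(
          sample = pick$sample[k], gene = pick$gene[k], value = tab$ct[hit]))
      }
    }
    list(table = tab,
         truth = data.frame(gene = cfg$genes, fold_true = cfg$fold),
         outliers = outliers)
  })
}
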