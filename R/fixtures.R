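# Synthetic data generation: a labeled expression compendium with
# planted marker genes, decoys targeting each signature filter,
# auxiliary summaries (cancer cell line / bulk tumor), gene sets,
# external validation sets, and a synthetic TIL10-style signature
# matrix. Everything is generated in code; no real cohort data ships
# with the package.

type_abbrev <- function() {
  c(B.cells = "B", Macrophages.M1 = "M1", Macrophages.M2 = "M2",
    Monocytes = "MO", Neutrophils = "NE", NK.cells = "NK",
    T.cells.CD4 = "C4", T.cells.CD8 = "C8", Tregs = "TR",
    Dendritic.cells = "DC")
}

# Draw one expression block for a set of libraries given the gene plan.
# Owned genes (markers/decoys/curated) are high in their owner's
# libraries and low-noise elsewhere; background genes are broad-range
# iid; a few housekeeping-like genes carry most of the TPM mass so that
# renormalization barely rescales the planted levels.
synth_expr <- function(plan, labels, noise_sd = 0.25) {
  n_g <- nrow(plan)
  n_l <- length(labels)
  X <- matrix(0, n_g, n_l, dimnames = list(plan$gene, names(labels)))
  owned <- !is.na(plan$owner)
  # low, widely spread out-of-type expression (log2 in [-6, 1]) so the
  # three-bin quantizer splits the low cluster, not the high one
  X[owned, ] <- 2^stats::runif(sum(owned) * n_l, -6, 1)
  for (i in which(owned)) {
    in_libs <- labels == plan$owner[i]
    if (any(in_libs))
      X[i, in_libs] <- plan$base[i] * 2^stats::rnorm(sum(in_libs), 0, noise_sd)
  }
  bg <- plan$class == "background"
  X[bg, ] <- 2^stats::runif(sum(bg) * n_l, 6, 11.5)
  hk <- plan$class == "housekeeping"
  X[hk, ] <- plan$base[hk] * 2^stats::rnorm(sum(hk) * n_l, 0, 0.1)
  tg <- plan$class == "tumor_gene"
  if (any(tg)) {
    X[tg, ] <- 2^stats::runif(sum(tg) * n_l, -6, 1)
    tl <- labels == "Tumor"
    if (any(tl))
      X[tg, tl] <- plan$base[tg] * 2^stats::rnorm(sum(tg) * sum(tl), 0, 0.1)
  }
  ps <- plan$class == "psmb2"
  if (any(ps)) {
    mult <- plan$psmb2_mult[[which(ps)]]
    X[ps, ] <- 500 * ifelse(labels %in% names(mult), mult[labels], 1) *
      2^stats::rnorm(n_l, 0, 0.05)
  }
  X
}

# Gene plan shared by the compendium and the external data sets.
synth_gene_plan <- function(n_markers = 12, n_background = 300) {
  types <- immune_cell_types()
  ab <- type_abbrev()
  mk <- function(prefix, owners, per, base_lo, base_hi) {
    do.call(rbind, lapply(owners, function(ct) {
      data.frame(gene = paste0(prefix, ab[ct], sprintf("%02d", seq_len(per))),
                 class = prefix_class(prefix), owner = ct,
                 base = stats::runif(per, base_lo, base_hi),
                 stringsAsFactors = FALSE)
    }))
  }
  prefix_class <- function(p)
    c(MK = "marker", DGS = "decoy_geneset", DRG = "decoy_range",
      DTH = "decoy_ccle", DLT = "decoy_tcga")[[p]]
  plan <- rbind(
    mk("MK", types, n_markers, 150, 400),
    mk("DGS", types, 2, 150, 400),
    mk("DRG", types, 1, 900, 1300),
    mk("DTH", types[1:5], 1, 150, 400),
    mk("DLT", types[6:10], 1, 150, 400)
  )
  curated <- data.frame(gene = .rmgenes_default, class = "curated",
                        owner = rep(types, length.out = 17),
                        base = stats::runif(17, 150, 400),
                        stringsAsFactors = FALSE)
  background <- data.frame(gene = sprintf("BG%03d", seq_len(n_background)),
                           class = "background", owner = NA, base = NA,
                           stringsAsFactors = FALSE)
  hk <- data.frame(gene = sprintf("HK%02d", 1:10), class = "housekeeping",
                   owner = NA, base = 2^stats::runif(10, 15.5, 16.5),
                   stringsAsFactors = FALSE)
  tumor_genes <- data.frame(gene = sprintf("TUM%02d", 1:20),
                            class = "tumor_gene", owner = NA,
                            base = stats::runif(20, 500, 2000),
                            stringsAsFactors = FALSE)
  psmb2 <- data.frame(gene = "PSMB2", class = "psmb2", owner = NA,
                      base = NA, stringsAsFactors = FALSE)
  plan <- rbind(plan, curated, background, hk, tumor_genes, psmb2)
  # per-type mRNA-content multipliers carried by the housekeeping gene
  plan$psmb2_mult <- vector("list", nrow(plan))
  plan$psmb2_mult[[which(plan$class == "psmb2")]] <-
    stats::setNames(2^stats::rnorm(length(types), 0, 0.5), types)
  plan
}

#' Generate the synthetic fixture bundle
#'
#' Builds a fully synthetic labeled compendium (ten immune cell types
#' with `libs_per_type` libraries each plus one tumor library), with
#' planted marker genes of known identity, decoy genes targeting each
#' signature filter (gene-set cross-listing, expression range above
#' 700 TPM, high cancer-cell-line expression, low bulk-tumor support),
#' the curated blacklist symbols as genuine type-specific genes, a
#' PSMB2 housekeeping gene encoding per-type mRNA content, plus the
#' auxiliary inputs the signature pipeline consumes: cancer cell line
#' and bulk-tumor expression summaries, a gene-set compendium, two
#' external labeled data sets, and simulated mixtures with known
#' fractions.
#'
#' @param seed Integer seed; the whole bundle is a deterministic
#'   function of it.
#' @param libs_per_type Libraries per immune cell type (default 3).
#' @param n_markers Planted markers per cell type (default 12).
#' @param n_background Background genes (default 300).
#' @param n_mixtures Simulated mixtures for the correlation filter
#'   (default 50).
#' @param dir Optional directory; when given, compendium, mixtures,
#'   truth, gene sets, summaries and alias map are written as TSVs.
#' @return List with `compendium`, `gene_plan`, `planted` (gene ->
#'   owner for planted marker-like genes), `gene_sets`, `ccle_summary`,
#'   `tcga_summary`, `external`, `mixtures` (`expr`, `fractions`),
#'   `scaling`, `alias_map`.
#' @export
make_fixtures <- function(seed = 42, libs_per_type = 3, n_markers = 12,
                          n_background = 300, n_mixtures = 50, dir = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  types <- immune_cell_types()
  plan <- synth_gene_plan(n_markers, n_background)
  labels <- c(rep(types, each = libs_per_type), "Tumor")
  names(labels) <- c(paste0(rep(type_abbrev(), each = libs_per_type),
                            "_lib", seq_len(libs_per_type)), "Tumor_lib")
  dataset <- c(rep(paste0("d", seq_len(libs_per_type)),
                   times = length(types)), "d1")
  X <- synth_expr(plan, labels)
  X <- sweep(X, 2, colSums(X), "/") * 1e6
  C <- labeled_compendium(X, labels, dataset)

  # auxiliary tumor-expression summaries over the same gene universe
  ccle <- matrix(stats::runif(nrow(plan) * 5, 2, 6), nrow(plan), 5,
                 dimnames = list(plan$gene, paste0("line", 1:5)))
  ccle[plan$class == "decoy_ccle", ] <-
    stats::runif(sum(plan$class == "decoy_ccle") * 5, 7.5, 10)
  tcga <- stats::setNames(stats::runif(nrow(plan), 1.5, 30), plan$gene)
  tcga[plan$class == "decoy_tcga"] <- 0.3

  # gene sets: one per type holding its planted markers; decoys listed
  # under the *next* type; one Treg marker listed in a CD4 set (the
  # exemption must keep it)
  gs <- do.call(rbind, lapply(seq_along(types), function(i) {
    ct <- types[i]
    own <- plan$gene[plan$class == "marker" & plan$owner == ct]
    nxt <- types[i %% length(types) + 1]
    dec <- plan$gene[plan$class == "decoy_geneset" & plan$owner == ct]
    rbind(data.frame(set = paste0("SET_", ct), cell_type = ct, gene = own,
                     stringsAsFactors = FALSE),
          data.frame(set = paste0("SET_", nxt), cell_type = nxt,
                     gene = dec, stringsAsFactors = FALSE))
  }))
  treg_mk <- plan$gene[plan$class == "marker" & plan$owner == "Tregs"][1]
  gs <- rbind(gs, data.frame(set = "SET_CD4_extra",
                             cell_type = "T.cells.CD4", gene = treg_mk,
                             stringsAsFactors = FALSE))

  # two external labeled data sets (no tumor library)
  external <- lapply(1:2, function(d) {
    lab <- rep(types, each = 2)
    names(lab) <- paste0("ext", d, "_", seq_along(lab))
    E <- synth_expr(plan, lab)
    E <- sweep(E, 2, colSums(E), "/") * 1e6
    labeled_compendium(E, lab, rep(paste0("ext", d), length(lab)))
  })

  # simulated mixtures with known fractions (for the correlation filter
  # and for recovery tests)
  profiles <- vapply(types, function(ct)
    apply(X[, labels == ct, drop = FALSE], 1, stats::median),
    numeric(nrow(X)))
  profiles <- cbind(profiles, Tumor = X[, labels == "Tumor"])
  fr <- vapply(seq_len(n_mixtures), function(i)
    simulate_fractions(length(types), stats::runif(1, 0, 0.8), types),
    numeric(length(types) + 1))
  rownames(fr) <- c(types, "Tumor")
  mix <- vapply(seq_len(n_mixtures), function(i)
    simulate_mixture(profiles, fr[, i], Inf), numeric(nrow(profiles)))
  dimnames(mix) <- list(rownames(X), paste0("mix", seq_len(n_mixtures)))

  planted <- plan$owner[plan$class %in% c("marker", "curated")]
  names(planted) <- plan$gene[plan$class %in% c("marker", "curated")]

  alias_map <- data.frame(old = c("MKB1-OLD", "PSMB2P", "HKA"),
                          new = c("MKB01", "PSMB2", "HK01"),
                          stringsAsFactors = FALSE)

  out <- list(compendium = C, gene_plan = plan, planted = planted,
              gene_sets = gs, ccle_summary = ccle, tcga_summary = tcga,
              external = external,
              mixtures = list(expr = mix, fractions = fr,
                              profiles = profiles),
              scaling = mrna_scaling_factors(C), alias_map = alias_map)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_matrix(X, file.path(dir, "compendium.tsv"))
    utils::write.table(data.frame(library = colnames(X),
                                  cell_type = labels, dataset = dataset),
                       file.path(dir, "compendium_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_expression_matrix(mix, file.path(dir, "mixtures.tsv"))
    write_expression_matrix(fr, file.path(dir, "mixture_truth.tsv"),
                            id_col = "cell_type")
    utils::write.table(out$alias_map, file.path(dir, "alias_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  out
}

#' Synthetic TIL10-style signature matrix
#'
#' A deterministic, fully synthetic stand-in for a published ten-type
#' signature matrix, used for bookkeeping, examples, and tests. It has
#' 170 genes: 153 synthetic type-specific markers plus the 17 curated
#' blacklist symbols. Blacklist genes carry an additional shared
#' moderate expression component across all cell types (emulating their
#' documented variable, cross-reactive expression), so removing them
#' yields a better-conditioned matrix.
#'
#' @return Numeric matrix, 170 genes x 10 cell types.
#' @export
#' @examples
#' S <- til10_synthetic()
#' dim(S)
#' nrow(apply_gene_blacklists(S, "default"))
til10_synthetic <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(1706)
  types <- immune_cell_types()
  ab <- type_abbrev()
  per_type <- c(16, 16, 16, rep(15, 7))
  genes <- unlist(lapply(seq_along(types), function(i)
    paste0("SG", ab[types[i]], sprintf("%02d", seq_len(per_type[i])))))
  owner <- rep(types, times = per_type)
  S <- matrix(2^stats::rnorm(length(genes) * length(types), 0, 0.7),
              length(genes), length(types),
              dimnames = list(genes, types))
  for (i in seq_along(genes))
    S[i, owner[i]] <- 2^(7 + stats::rnorm(1, 0, 0.4))
  cur_owner <- rep(types, length.out = 17)
  Cur <- matrix(2^(5 + stats::rnorm(17 * length(types), 0, 0.3)),
                17, length(types),
                dimnames = list(.rmgenes_default, types))
  for (i in 1:17) Cur[i, cur_owner[i]] <- 2^(7 + stats::rnorm(1, 0, 0.4))
  # the tumor-blacklist symbols not already in the curated list are
  # ordinary signature genes, as in the published matrix: spread them
  # across cell types in place of synthetic symbols
  tum_only <- setdiff(.rmgenes_tumor, .rmgenes_default)
  rn <- rownames(S)
  rn[seq(1, by = 10, length.out = length(tum_only))] <- tum_only
  rownames(S) <- rn
  rbind(S, Cur)
}
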