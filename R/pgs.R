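# Polygenic score construction, ancestry principal components, and the
# group-descriptive statistics used to characterize gene-environment
# correlation.

#' Genotype panel
#'
#' An individuals-by-SNPs matrix of additive allele counts (0/1/2) together
#' with per-SNP GWAS effect-size weights. Fractional dosage values are
#' accepted but flagged, since downstream score construction is
#' coding-agnostic.
#'
#' @param genotypes Numeric matrix, rows = individuals, columns = SNPs.
#' @param weights Numeric vector of per-SNP effect sizes (GWAS betas),
#'   length `ncol(genotypes)`.
#' @param snp_ids Optional SNP identifiers; default colnames or snp1..snpJ.
#' @param ids Optional individual identifiers.
#' @return Object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(genotypes, weights, snp_ids = NULL, ids = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.numeric(genotypes), is.numeric(weights))
  if (ncol(genotypes) != length(weights))
    stop("genotype_panel: ", ncol(genotypes), " SNP columns but ",
         length(weights), " weights")
  if (any(!is.finite(weights))) stop("genotype_panel: weights must be finite")
  if (anyNA(genotypes)) stop("genotype_panel: missing genotypes not supported")
  if (any(genotypes < 0 | genotypes > 2))
    stop("genotype_panel: allele counts/dosages must lie in [0, 2]")
  dosage <- !all(genotypes %in% c(0, 1, 2))
  if (dosage)
    warning("genotype_panel: fractional dosages detected; treating as additive dosage")
  if (is.null(snp_ids))
    snp_ids <- colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(ids))
    ids <- rownames(genotypes) %||% paste0("id", seq_len(nrow(genotypes)))
  dimnames(genotypes) <- list(ids, snp_ids)
  structure(list(genotypes = genotypes, weights = weights,
                 snp_ids = snp_ids, ids = ids, dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs%s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (x$dosage) " (dosage)" else ""))
  invisible(x)
}

#' Polygenic score
#'
#' Per-individual weighted sum of allele counts, raw and standardized
#' within the provided sample: raw_i = sum_j W_j G_ij; standardized =
#' (raw - mean) / SD.
#'
#' @param panel A `genotype_panel`.
#' @return Data frame with `id`, `raw`, `pgs` (standardized, mean 0 / SD 1).
#' @export
compute_pgs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  raw <- drop(panel$genotypes %*% panel$weights)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("compute_pgs: raw scores have zero variance; cannot standardize")
  data.frame(id = panel$ids, raw = raw, pgs = (raw - mean(raw)) / s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ancestry principal components
#'
#' Top-k principal components of the column-standardized genotype matrix
#' (each SNP centred and scaled by its count mean/SD; zero-variance SNPs
#' dropped). Component signs are fixed by making each loading vector's
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param panel A `genotype_panel`.
#' @param k Number of components (default 10).
#' @return List of class `"ancestry_pcs"`: `scores` (n x k matrix, columns
#'   PC1..PCk), `sdev` (component standard deviations, non-increasing),
#'   `var_explained`, `dropped_snps`.
#' @export
ancestry_pcs <- function(panel, k = 10L) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$genotypes
  n <- nrow(G)
  sds <- apply(G, 2L, stats::sd)
  keep <- sds > 0
  if (k >= min(n, sum(keep)))
    stop("ancestry_pcs: k must be smaller than both n and the number of ",
         "variable SNPs")
  Z <- scale(G[, keep, drop = FALSE])
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # deterministic sign: largest-|loading| entry of each right vector positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- panel$ids
  sdev <- sv$d[seq_len(k)] / sqrt(n - 1)
  structure(list(scores = scores, sdev = sdev,
                 var_explained = sdev^2 / sum((svd(Z, 0, 0)$d)^2 / (n - 1)),
                 dropped_snps = panel$snp_ids[!keep]),
            class = "ancestry_pcs")
}

#' @export
print.ancestry_pcs <- function(x, ...) {
  cat("Ancestry PCs:", ncol(x$scores), "components,",
      nrow(x$scores), "individuals\n")
  cat("  proportion of variance:",
      paste0(sprintf("%.3f", x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Two-group gap in a score
#'
#' Pooled-variance two-sample t test (df = n - 2) of a score across a
#' binary grouping, with Cohen's d (pooled SD) and a 95% Wald CI on d.
#'
#' @param scores Numeric vector.
#' @param group Binary group membership (0/1 or logical), same length.
#' @return List: `mean_diff` (group 0 minus group 1), `t`, `df`, `p`,
#'   `cohens_d`, `ci` (on d).
#' @export
group_gap <- function(scores, group) {
  group <- as.integer(as.logical(group))
  stopifnot(length(scores) == length(group))
  x0 <- scores[group == 0]; x1 <- scores[group == 1]
  if (length(x0) < 2L || length(x1) < 2L)
    stop("group_gap: each group needs at least two members")
  tt <- stats::t.test(x0, x1, var.equal = TRUE)
  n0 <- length(x0); n1 <- length(x1)
  sp <- sqrt(((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) /
               (n0 + n1 - 2))
  d <- (mean(x0) - mean(x1)) / sp
  se_d <- sqrt((n0 + n1) / (n0 * n1) + d^2 / (2 * (n0 + n1)))
  list(mean_diff = mean(x0) - mean(x1),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = d,
       ci = d + c(-1, 1) * stats::qnorm(0.975) * se_d)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson r with the two-sided p-value from the t transform and a 95% CI
#' from the Fisher z transform, reported in the conventional
#' "r(df) = value, 95% CI [a, b]" style.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), non-constant.
#' @return List: `r`, `df`, `p`, `ci`, `n`, and `label` (formatted string).
#' @export
pearson_ci <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("pearson_ci: need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_ci: constant input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  list(r = r, df = unname(ct$parameter), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = length(x),
       label = sprintf("r(%d) = %.3f, p = %.3g, 95%% CI [%.3f, %.3f]",
                       unname(ct$parameter), r, ct$p.value,
                       ct$conf.int[1], ct$conf.int[2]))
}
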