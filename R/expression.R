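#' Acquisition filters for two-colour intensity data
#'
#' Applies the two acquisition rules: probes whose signal-to-noise ratio
#' (foreground/background) is below \code{snr_min} in every hybridisation are
#' deemed undetectable and removed (one passing hybridisation suffices for
#' survival); genes represented by several probes are collapsed to the most
#' abundant probe, i.e. the probe with the highest background-corrected
#' intensity averaged across all hybridisations. Values are background
#' corrected (foreground minus background, floored) and log2 transformed.
#'
#' @param raw Intensity data frame with columns hyb_id, array_id,
#'   print_block, dye, variety, probe_id, gene_id, foreground, background.
#' @param snr_min Signal-to-noise threshold (default 2).
#' @param floor Floor for the background-corrected intensity (default 1).
#' @return Data frame with columns hyb_id, array_id, print_block, dye,
#'   variety, gene_id, y (log2 background-corrected intensity). Attributes
#'   \code{n_probes_in}, \code{n_probes_snr_removed},
#'   \code{n_probes_collapsed} carry the filter tallies.
#' @export
acquire <- function(raw, snr_min = 2.0, floor = 1) {
  need <- c("hyb_id", "array_id", "print_block", "dye", "variety",
            "probe_id", "gene_id", "foreground", "background")
  if (!all(need %in% names(raw)))
    stop("intensity table needs columns: ", paste(need, collapse = ", "))
  if (!nrow(raw)) stop("empty intensity table")
  ratio <- raw$foreground / raw$background
  ratio[raw$background <= 0] <- Inf
  detectable <- tapply(ratio >= snr_min, raw$probe_id, any)
  keep_probes <- names(detectable)[detectable]
  n_in <- length(detectable)
  if (!length(keep_probes))
    stop("all probes below the signal-to-noise threshold")
  d <- raw[raw$probe_id %in% keep_probes, , drop = FALSE]
  corrected <- pmax(d$foreground - d$background, floor)
  # most abundant probe per gene, averaged across hybridisations
  mean_int <- tapply(corrected, d$probe_id, mean)
  probe_gene <- tapply(d$gene_id, d$probe_id, function(x) x[1])
  best <- tapply(seq_along(mean_int), probe_gene[names(mean_int)], function(i) {
    ix <- i[order(-mean_int[i], names(mean_int)[i])]
    names(mean_int)[ix[1]]
  })
  keep <- d$probe_id %in% unlist(best)
  out <- d[keep, c("hyb_id", "array_id", "print_block", "dye", "variety", "gene_id")]
  out$y <- log2(corrected[keep])
  rownames(out) <- NULL
  attr(out, "n_probes_in") <- n_in
  attr(out, "n_probes_snr_removed") <- n_in - length(keep_probes)
  attr(out, "n_probes_collapsed") <- length(keep_probes) - length(unlist(best))
  out
}

# Per-gene block bookkeeping for the EM-REML fit. V is block diagonal by gene
# because all random effects (G, AG, DG, VG) nest within gene; genes whose
# rows show the same (array, dye, variety, comparison-cell) sequence share a
# block pattern, so V-inverse and all trace terms are computed once per
# pattern (once in total for a balanced loop design).
build_reml_structure <- function(d) {
  cellf <- interaction(d$array_id, d$print_block, d$dye, drop = TRUE, lex.order = TRUE)
  d$cell <- as.integer(cellf)
  d$arr <- as.integer(factor(d$array_id))
  d$dyei <- as.integer(factor(d$dye))
  d$vari <- as.integer(factor(d$variety))
  genef <- factor(d$gene_id)
  ord <- order(genef, d$arr, d$dyei, d$vari)
  d <- d[ord, ]
  genef <- genef[ord]
  rows_by_gene <- split(seq_len(nrow(d)), genef)
  keys <- vapply(rows_by_gene, function(r)
    paste(d$arr[r], d$dyei[r], d$vari[r], d$cell[r], collapse = ";"),
    character(1))
  pat_of_gene <- match(keys, unique(keys))
  patterns <- lapply(which(!duplicated(keys)), function(gidx) {
    r <- rows_by_gene[[gidx]]
    n <- length(r)
    same <- function(v) outer(v, v, "==") * 1
    list(n = n,
         J = matrix(1, n, n),
         S_arr = same(d$arr[r]),
         S_dye = same(d$dyei[r]),
         S_var = same(d$vari[r]),
         cell = d$cell[r],
         ucell = sort(unique(d$cell[r])),
         arr_loc = d$arr[r], dye_loc = d$dyei[r], var_loc = d$vari[r])
  })
  list(d = d, genef = genef, rows_by_gene = rows_by_gene,
       pat_of_gene = pat_of_gene, patterns = patterns,
       n_cells = nlevels(cellf), cell_levels = levels(cellf),
       varieties = levels(factor(d$variety)))
}

#' Fit the mixed-model ANOVA normalization by EM-REML
#'
#' Fits the two-colour normalization model
#' \deqn{y = \mu + C + G + AG + DG + VG + e}
#' where C is the fixed comparison-group effect (measurements from the same
#' array slide, printing block and dye channel), and gene (G), array-by-gene
#' (AG), dye-by-gene (DG), variety-by-gene (VG) and the residual are
#' independent zero-mean random effects. Variance components are estimated by
#' restricted maximum likelihood using an expectation-maximization scheme
#' (components truncated at zero; the REML log-likelihood is non-decreasing
#' across iterations), and the best linear unbiased predictions of all random
#' effects are returned. The VG solutions, reported on the intensity scale as
#' \eqn{\hat\mu + \hat G + \hat{VG}}, are the normalized mean expression of
#' each gene in each variety.
#'
#' @param data Output of \code{\link{acquire}} (columns array_id,
#'   print_block, dye, variety, gene_id, y).
#' @param tol Convergence tolerance on the relative change of every variance
#'   component (default 1e-6).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param verbose Print iteration progress.
#' @return Object of class \code{normalization_fit}: mu,
#'   comparison_group_effects, variance_components (gene, array_gene,
#'   dye_gene, variety_gene, residual), gene_solutions,
#'   variety_gene_solutions (gene x variety), normalized_expression
#'   (mu + G + VG), converged, iterations, loglik_trace.
#' @export
fit_normalization_model <- function(data, tol = 1e-6, max_iter = 2000,
                                    verbose = FALSE) {
  need <- c("array_id", "print_block", "dye", "variety", "gene_id", "y")
  if (!all(need %in% names(data)))
    stop("normalization input needs columns: ", paste(need, collapse = ", "))
  if (length(unique(data$gene_id)) < 2) stop("need >= 2 genes")
  if (length(unique(data$variety)) < 2) stop("need >= 2 varieties")

  st <- build_reml_structure(data)
  d <- st$d
  n <- nrow(d)
  y <- d$y
  m_genes <- nlevels(st$genef)
  c_cells <- st$n_cells

  # random-factor level indices per row
  gidx <- as.integer(st$genef)
  f_gene <- gidx
  f_ag <- (gidx - 1L) * max(d$arr) + d$arr
  f_dg <- (gidx - 1L) * max(d$dyei) + d$dyei
  f_vg <- (gidx - 1L) * max(d$vari) + d$vari
  fac <- list(gene = f_gene, array_gene = f_ag, dye_gene = f_dg,
              variety_gene = f_vg)
  q_f <- vapply(fac, function(f) length(unique(f)), numeric(1))

  y_by_gene <- lapply(st$rows_by_gene, function(r) y[r])
  pat_count <- tabulate(st$pat_of_gene, nbins = length(st$patterns))

  vy <- stats::var(y)
  s2 <- c(gene = vy / 4, array_gene = vy / 8, dye_gene = vy / 8,
          variety_gene = vy / 8, residual = vy / 2)
  floor_v <- 1e-12
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0

  repeat {
    iter <- iter + 1
    # per-pattern V inverse and trace pieces
    pinfo <- lapply(st$patterns, function(p) {
      V <- s2[["gene"]] * p$J + s2[["array_gene"]] * p$S_arr +
        s2[["dye_gene"]] * p$S_dye + s2[["variety_gene"]] * p$S_var
      diag(V) <- diag(V) + s2[["residual"]]
      ch <- chol(V)
      Vi <- chol2inv(ch)
      A <- rowsum(Vi, p$cell)                 # local cells x n (sorted by cell)
      list(Vi = Vi, logdet = 2 * sum(log(diag(ch))), A = A,
           XX = rowsum(t(A), p$cell),          # local X'V^-1 X
           X2 = A %*% t(A),                    # local X'V^-2 X
           t1 = c(gene = sum(Vi * p$J),
                  array_gene = sum(Vi * p$S_arr),
                  dye_gene = sum(Vi * p$S_dye),
                  variety_gene = sum(Vi * p$S_var)),
           trVi = sum(diag(Vi)),
           C_f = list(gene = rowsum(t(A), rep(1L, p$n)),
                      array_gene = rowsum(t(A), p$arr_loc),
                      dye_gene = rowsum(t(A), p$dye_loc),
                      variety_gene = rowsum(t(A), p$var_loc)))
    })
    XtViX <- matrix(0, c_cells, c_cells)
    XtViy <- numeric(c_cells)
    logdetV <- 0
    for (p in seq_along(pinfo)) {
      uc <- st$patterns[[p]]$ucell
      XtViX[uc, uc] <- XtViX[uc, uc] + pat_count[p] * pinfo[[p]]$XX
      logdetV <- logdetV + pat_count[p] * pinfo[[p]]$logdet
    }
    for (g in seq_len(m_genes)) {
      p <- st$pat_of_gene[g]
      uc <- st$patterns[[p]]$ucell
      XtViy[uc] <- XtViy[uc] + pinfo[[p]]$A %*% y_by_gene[[g]]
    }
    chA <- chol(XtViX)
    beta <- backsolve(chA, forwardsolve(t(chA), XtViy))
    Ainv <- chol2inv(chA)
    logdetA <- 2 * sum(log(diag(chA)))

    Py <- numeric(n)
    for (g in seq_len(m_genes)) {
      p <- st$pat_of_gene[g]
      r <- st$rows_by_gene[[g]]
      resid <- y_by_gene[[g]] - beta[st$patterns[[p]]$cell]
      Py[r] <- pinfo[[p]]$Vi %*% resid
    }
    yPy <- sum(y * Py)
    loglik <- -0.5 * (logdetV + logdetA + yPy)
    loglik_trace <- c(loglik_trace, loglik)
    if (verbose) message(sprintf("iter %d  logLik %.6f", iter, loglik))

    # quadratic forms and traces per random factor
    ss_f <- vapply(fac, function(f) sum(rowsum(Py, f)^2), numeric(1))
    tr_f <- stats::setNames(numeric(4), names(fac))
    for (fn in names(fac)) {
      t1 <- 0; mterm <- 0
      for (p in seq_along(pinfo)) {
        uc <- st$patterns[[p]]$ucell
        Cf <- pinfo[[p]]$C_f[[fn]]
        t1 <- t1 + pat_count[p] * pinfo[[p]]$t1[[fn]]
        mterm <- mterm + pat_count[p] *
          sum((Cf %*% Ainv[uc, uc, drop = FALSE]) * Cf)
      }
      tr_f[fn] <- t1 - mterm
    }
    trVi_tot <- 0; X2m <- 0
    for (p in seq_along(pinfo)) {
      uc <- st$patterns[[p]]$ucell
      trVi_tot <- trVi_tot + pat_count[p] * pinfo[[p]]$trVi
      X2m <- X2m + pat_count[p] * sum(Ainv[uc, uc] * pinfo[[p]]$X2)
    }
    trP <- trVi_tot - X2m

    s2_new <- s2
    for (fn in names(fac))
      s2_new[[fn]] <- s2[[fn]] + s2[[fn]]^2 * (ss_f[[fn]] - tr_f[[fn]]) / q_f[[fn]]
    s2_new[["residual"]] <- s2[["residual"]] +
      s2[["residual"]]^2 * (sum(Py^2) - trP) / n
    s2_new <- pmax(s2_new, floor_v)

    delta <- max(abs(s2_new - s2) / pmax(s2, 1e-8))
    s2 <- s2_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) {
      warning("EM-REML did not converge in ", max_iter, " iterations")
      break
    }
  }

  # final solutions at the converged components (Py from the last iteration)
  u <- lapply(names(fac), function(fn) {
    sc <- rowsum(Py, fac[[fn]])
    stats::setNames(as.numeric(s2[[fn]] * sc), rownames(sc))
  })
  names(u) <- names(fac)
  mu <- mean(beta)
  gene_levels <- levels(st$genef)
  gene_solutions <- stats::setNames(numeric(m_genes), gene_levels)
  gene_solutions[as.integer(names(u$gene))] <- u$gene
  names(gene_solutions) <- gene_levels

  var_levels <- levels(factor(d$variety))
  n_var <- length(var_levels)
  vg <- matrix(0, m_genes, n_var, dimnames = list(gene_levels, var_levels))
  lev <- as.integer(names(u$variety_gene))
  g_of <- (lev - 1L) %/% max(d$vari) + 1L
  v_of <- (lev - 1L) %% max(d$vari) + 1L
  # d$vari was coded from factor(d$variety): recover the level order
  vmap <- levels(factor(d$variety))
  vg[cbind(g_of, v_of)] <- u$variety_gene

  normalized <- mu + gene_solutions + vg

  structure(list(
    mu = mu,
    comparison_group_effects = stats::setNames(as.numeric(beta), st$cell_levels),
    variance_components = s2,
    gene_solutions = gene_solutions,
    variety_gene_solutions = vg,
    normalized_expression = normalized,
    converged = converged,
    iterations = iter,
    loglik_trace = loglik_trace), class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("normalization_fit: %d genes x %d varieties, %s after %d EM iterations\n",
              nrow(x$normalized_expression), ncol(x$normalized_expression),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("variance components:\n")
  print(round(x$variance_components, 5))
  invisible(x)
}

#' The seven differential-expression contrasts
#'
#' Linear combinations of the per-variety normalized expression:
#' DE1 (black vs white within piebald) = PBB - PBW;
#' DE2 (piebald vs recessive within black) = PBB - RSB;
#' DE3 (piebald vs normal within white) = PBW - NOR;
#' DE4 (piebald vs recessive within white) = PBW - RSW;
#' DE5 (piebald vs others within white) = PBW - (NOR + RSW)/2;
#' DE6 (piebald vs non-piebald) = (PBW + PBB)/2 - (NOR + RSW + RSB)/3;
#' DE7 (black vs white) = (PBB + RSB)/2 - (NOR + PBW + RSW)/3.
#'
#' @param fit A \code{normalization_fit}, or a numeric gene x variety matrix
#'   with the five variety columns.
#' @return Data frame with gene_id and DE1..DE7 (log2 units).
#' @export
compute_contrasts <- function(fit) {
  x <- if (inherits(fit, "normalization_fit")) fit$normalized_expression else fit
  if (!is.matrix(x)) stop("expected a normalization_fit or a gene x variety matrix")
  missing_v <- setdiff(VARIETIES, colnames(x))
  if (length(missing_v))
    stop("missing variety: ", paste(missing_v, collapse = ", "))
  nor <- x[, "NOR"]; pbw <- x[, "PBW"]; pbb <- x[, "PBB"]
  rsw <- x[, "RSW"]; rsb <- x[, "RSB"]
  data.frame(gene_id = rownames(x),
             DE1 = pbb - pbw,
             DE2 = pbb - rsb,
             DE3 = pbw - nor,
             DE4 = pbw - rsw,
             DE5 = pbw - (nor + rsw) / 2,
             DE6 = (pbw + pbb) / 2 - (nor + rsw + rsb) / 3,
             DE7 = (pbb + rsb) / 2 - (nor + pbw + rsw) / 3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes per contrast
#'
#' Standardizes each contrast across genes and flags a gene in a contrast
#' when its absolute z-score reaches \code{sd_threshold} (default 2.57,
#' corresponding to a nominal two-tailed P < 0.01).
#'
#' @param contrasts Output of \code{\link{compute_contrasts}}.
#' @param sd_threshold Standard-deviation cut-off (default 2.57).
#' @return Data frame with DE1..DE7, z-scores (z_DE1..z_DE7), flags
#'   (de_DE1..de_DE7) and n_de_contrasts.
#' @export
call_de <- function(contrasts, sd_threshold = 2.57) {
  de_cols <- paste0("DE", 1:7)
  if (!all(de_cols %in% names(contrasts)))
    stop("expected columns DE1..DE7")
  if (nrow(contrasts) < 3) stop("need >= 3 genes to standardize contrasts")
  out <- contrasts
  flags <- matrix(FALSE, nrow(contrasts), 7,
                  dimnames = list(NULL, paste0("de_", de_cols)))
  for (k in seq_along(de_cols)) {
    v <- contrasts[[de_cols[k]]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("zero standard deviation in ", de_cols[k], "; no gene flagged")
      z <- rep(0, length(v))
    } else {
      z <- (v - mean(v)) / s
      flags[, k] <- abs(z) >= sd_threshold
    }
    out[[paste0("z_", de_cols[k])]] <- z
  }
  for (k in seq_along(de_cols)) out[[colnames(flags)[k]]] <- flags[, k]
  out$n_de_contrasts <- rowSums(flags)
  out
}

#' Genes differentially expressed in at least a given number of contrasts
#'
#' @param de_results Output of \code{\link{call_de}}.
#' @param min_contrasts Minimum number of DE contrasts (default 4).
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de_results, min_contrasts = 4) {
  de_results$gene_id[de_results$n_de_contrasts >= min_contrasts]
}

#' Contrast correlations and piebald colour categories
#'
#' Pearson correlations across genes for the 21 contrast pairs, the per-gene
#' piebald score (mean of DE3, DE5 and DE6 -- the contrasts comparing piebald
#' against non-piebald tissue), and the network colour category: a gene is
#' over- (red) or under-expressed (green) when the across-gene z-score of its
#' piebald score passes the threshold, unchanged (orange) otherwise, and
#' absent (blue) when it is not represented on the array.
#'
#' @param de_results Output of \code{\link{call_de}} (or
#'   \code{\link{compute_contrasts}}).
#' @param sd_threshold Threshold on the piebald-score z (default 2.57).
#' @param all_genes Optional vector of gene ids; genes not present in
#'   \code{de_results} are reported with colour \code{"absent"}.
#' @return List with \code{correlations} (7x7 matrix) and \code{colours}
#'   (data frame: gene_id, piebald_score, score_z, colour_category).
#' @export
contrast_correlations <- function(de_results, sd_threshold = 2.57,
                                  all_genes = NULL) {
  de_cols <- paste0("DE", 1:7)
  if (nrow(de_results) < 3) stop("need >= 3 genes")
  mat <- as.matrix(de_results[, de_cols])
  correlations <- stats::cor(mat)
  score <- rowMeans(mat[, c("DE3", "DE5", "DE6")])
  s <- stats::sd(score)
  z <- if (is.na(s) || s == 0) rep(0, length(score)) else (score - mean(score)) / s
  colour <- ifelse(z >= sd_threshold, "over",
                   ifelse(z <= -sd_threshold, "under", "unchanged"))
  colours <- data.frame(gene_id = de_results$gene_id,
                        piebald_score = score, score_z = z,
                        colour_category = colour, stringsAsFactors = FALSE)
  if (!is.null(all_genes)) {
    absent <- setdiff(all_genes, colours$gene_id)
    if (length(absent))
      colours <- rbind(colours,
                       data.frame(gene_id = absent, piebald_score = NA_real_,
                                  score_z = NA_real_, colour_category = "absent",
                                  stringsAsFactors = FALSE))
  }
  list(correlations = correlations, colours = colours)
}
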