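# Community summaries and the factorial statistics applied to them:
# aggregation of classified counts to cluster / phylum / family rank,
# relative abundances, Shannon diversity, balanced factorial ANOVA and
# Tukey HSD contrasts with a compact letter display.

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums per-sample ASV counts by the label each ASV carries at the
#' requested rank (`cluster` from the assignment table, `phylum`/`family`
#' parsed from its lineage). ASVs lacking an assignment, or with an empty
#' label at that rank, are pooled under `"unassigned"`. Per-sample totals
#' are conserved.
#'
#' @param counts Integer matrix, samples x ASVs (column names = ASV ids).
#' @param assignments Data.frame with `asv_id`, `cluster`, `lineage` (from
#'   [classify_asv()]).
#' @param rank `"cluster"`, `"phylum"` or `"family"`.
#' @return Integer matrix, samples x labels, with attribute `rank`.
#' @export
aggregate_counts <- function(counts, assignments,
                             rank = c("cluster", "phylum", "family")) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stop2("counts must be non-negative")
  idx <- match(colnames(counts), assignments$asv_id)
  lab <- if (rank == "cluster") assignments$cluster[idx]
         else parse_lineage(ifelse(is.na(idx), "",
                                   assignments$lineage[idx]))[[rank]]
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  out <- t(rowsum(t(counts), group = lab))
  attr(out, "rank") <- rank
  out
}

#' Convert counts to relative abundances
#'
#' @param table Numeric matrix, samples x taxa, with positive row sums.
#' @return Matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  table <- as.matrix(table)
  tot <- rowSums(table)
  bad <- rownames(table)[tot <= 0] %||% which(tot <= 0)
  if (any(tot <= 0))
    .stop2("zero-total sample(s): ", paste(bad, collapse = ", "))
  sweep(table, 1, tot, "/")
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over non-zero proportions, computed with
#' [vegan::diversity()]. Natural log by default, matching the study's
#' index scale.
#'
#' @param counts Numeric vector (one sample) or matrix (samples x taxa).
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric vector of H values.
#' @export
#' @examples
#' shannon_index(rep(5, 4))  # log(4)
shannon_index <- function(counts, base = exp(1)) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    if (any(rowSums(counts) <= 0)) .stop2("sample with zero total")
    vegan::diversity(as.matrix(counts), index = "shannon", base = base)
  } else {
    if (sum(counts) <= 0) .stop2("sample with zero total")
    unname(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                            base = base))
  }
}

.check_balanced <- function(data, factors) {
  for (f in factors) {
    if (length(unique(data[[f]])) < 2)
      .stop2("factor '", f, "' needs >= 2 levels")
  }
  tab <- table(data[factors])
  if (any(tab == 0)) .stop2("design has empty cells; unbalanced designs are out of scope")
  if (length(unique(as.vector(tab))) != 1)
    .stop2("design is unbalanced; balanced complete designs only")
  invisible(TRUE)
}

#' Factorial analysis of variance on a balanced complete design
#'
#' Fits a fully crossed ANOVA (all main effects, optionally all
#' interactions) on a balanced complete design, where Type I/II/III sums
#' of squares coincide. F for a term with zero sum of squares is reported
#' as 0.
#'
#' @param data Data.frame holding response and factor columns.
#' @param response Name of the (numeric) response column.
#' @param factors Character vector of 1--3 factor column names.
#' @param interactions Include all interaction terms (default `TRUE`).
#' @return List with `table` (data.frame `term`, `df`, `sumsq`, `meansq`,
#'   `F`, `p`; last row `Residuals`) and `model` (the fitted `aov`).
#' @export
anova_factorial <- function(data, response, factors, interactions = TRUE) {
  if (length(factors) < 1 || length(factors) > 3)
    .stop2("1 to 3 factors supported")
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss)) .stop2("missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  .check_balanced(data, factors)
  rhs <- paste(factors, collapse = if (interactions) " * " else " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::aov(fml, data = data)
  s <- summary(fit)[[1]]
  term <- trimws(rownames(s))
  tab <- data.frame(term = term, df = s[["Df"]], sumsq = s[["Sum Sq"]],
                    meansq = s[["Mean Sq"]], F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  res <- tab$term == "Residuals"
  mse <- tab$meansq[res]
  dfe <- tab$df[res]
  # a term's SS is "zero" relative to the response scale (guards the
  # constant-response case, where numeric error leaves ~1e-30 residue)
  ss_floor <- 1e-12 * max(sum(tab$sumsq), .Machine$double.eps)
  for (i in which(!res)) {
    if (tab$sumsq[i] <= ss_floor) {
      tab$F[i] <- 0
      tab$p[i] <- 1
    } else if (mse > 0) {
      tab$F[i] <- tab$meansq[i] / mse
      tab$p[i] <- stats::pf(tab$F[i], tab$df[i], dfe, lower.tail = FALSE)
    } else {
      tab$F[i] <- Inf
      tab$p[i] <- 0
    }
  }
  list(table = tab, model = fit)
}

# compact letter display by insert-and-absorb over the significance graph
.compact_letters <- function(groups, sig_pairs) {
  cols <- list(setNames(rep(TRUE, length(groups)), groups))
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[a] && col[b]) {
        c1 <- col; c1[a] <- FALSE
        c2 <- col; c2[b] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop columns whose member set is a subset of another's
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && !drop[i] && !drop[j] &&
          all(!cols[[i]] | cols[[j]]) && !identical(cols[[i]], cols[[j]]))
        drop[i] <- TRUE
      if (i < j && !drop[i] && !drop[j] && identical(cols[[i]], cols[[j]]))
        drop[j] <- TRUE
    }
    cols <- cols[!drop]
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    members <- names(cols[[ci]])[cols[[ci]]]
    out[members] <- paste0(out[members], letters_pool[ci])
  }
  out
}

#' Tukey HSD contrasts with a compact letter display
#'
#' Studentized-range adjusted pairwise comparisons of the cell means of a
#' balanced design (all factor combinations treated as one-way cells, as
#' in the study's treatment-letter figures), plus a compact letter display
#' built by insert-and-absorb: two cells share a letter iff they are not
#' significantly different at `alpha`.
#'
#' @param data Data.frame holding response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Factor column names defining the cells.
#' @param alpha Significance level (default 0.05).
#' @return List with `pairwise` (data.frame `a`, `b`, `diff`, `lwr`,
#'   `upr`, `p_adj`), `letters` (named by cell) and `means` (named cell
#'   means, decreasing).
#' @export
tukey_hsd <- function(data, response, factors, alpha = 0.05) {
  data <- as.data.frame(data)
  .check_balanced(data, factors)
  cell <- interaction(data[factors], sep = ":", drop = TRUE, lex.order = TRUE)
  d <- data.frame(y = data[[response]], cell = cell)
  fit <- stats::aov(y ~ cell, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cell
  # pair (a, b) per row: TukeyHSD orders rows as combn(levels, 2) with the
  # later level first; rebuild from levels rather than parsing rownames,
  # which may themselves contain '-'
  pairs <- utils::combn(levels(d$cell), 2)
  stopifnot(ncol(pairs) == nrow(tk))
  pairwise <- data.frame(
    a = pairs[2, ], b = pairs[1, ],
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
  means <- sort(tapply(d$y, d$cell, mean), decreasing = TRUE)
  sig <- pairwise[which(pairwise$p_adj < alpha), c("a", "b"), drop = FALSE]
  letters <- .compact_letters(names(means), sig)
  list(pairwise = pairwise, letters = letters, means = means)
}
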