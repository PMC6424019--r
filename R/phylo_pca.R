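#' Parse a Newick tree, tolerating the loose published dialect
#'
#' Accepts strict Newick as well as the looser form sometimes found in
#' print: the whole tree wrapped in square brackets, sibling clades
#' juxtaposed with spaces instead of commas, and whitespace inside the
#' string. The normalized string is parsed with \pkg{ape}; singleton
#' (unifurcating) internal nodes arising from redundant parentheses are
#' collapsed, and polytomies are kept as printed. Missing branch lengths
#' are set to `default_brlen`.
#'
#' @param text Newick string, or a file path to one.
#' @param default_brlen branch length assigned where none is given
#'   (default 1).
#' @return an [ape::read.tree()] `phylo` object with branch lengths.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr$edge.length  # all 1
#' @export
parse_newick <- function(text, default_brlen = 1) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) &&
      file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = " ")
  s <- trimws(text)
  s <- gsub("\\*", "", s)
  s <- sub("\\.$", "", s)
  s <- sub("^\\[", "(", s)
  s <- sub("\\];?$", ")", s)
  if (lengths(regmatches(s, gregexpr("\\(", s))) !=
      lengths(regmatches(s, gregexpr("\\)", s))))
    stopf("unbalanced parentheses in Newick string")
  # insert the commas the loose dialect omits between adjacent siblings
  s <- gsub("\\)\\s*\\(", "),(", s)
  s <- gsub("([A-Za-z0-9_.'])\\s+\\(", "\\1,(", s)
  s <- gsub("\\)\\s+([A-Za-z0-9_.'])", "),\\1", s)
  s <- gsub("\\s+", "", s)
  if (!grepl(";$", s)) s <- paste0(s, ";")
  tree <- tryCatch(ape::read.tree(text = s),
                   error = function(e) NULL)
  if (is.null(tree)) stopf("could not parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  tree <- ape::collapse.singles(tree)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_brlen, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- default_brlen
  }
  tree
}

#' Brownian-motion covariance matrix induced by a tree
#'
#' C[i, j] is the shared root-to-MRCA branch length of tips i and j (the
#' diagonal holds root-to-tip depths). Restricted and ordered to the
#' requested tips.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tips tip labels to keep, in the desired order (default: all tips
#'   in tree order).
#' @return symmetric positive semi-definite matrix.
#' @export
phylo_covariance <- function(tree, tips = tree$tip.label) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stopf("tip(s) not in tree: %s", paste(unknown, collapse = ", "))
  C <- ape::vcv(tree)
  C[tips, tips, drop = FALSE]
}

#' Phylogenetically informed principal component analysis
#'
#' PCA of a specimens-by-traits matrix that accounts for the
#' non-independence of related species through the Brownian-motion
#' covariance C of the tree. The phylogenetic (GLS) mean is
#' a = (1' C^-1 1)^-1 1' C^-1 X, the evolutionary covariance
#' V = (X - 1a)' C^-1 (X - 1a) / (n - 1), eigendecomposed after rescaling
#' to unit diagonal in correlation mode (the default: morphometric traits
#' mix counts, percentages and unit-interval indexes, so correlation mode
#' puts them on one scale). Scores are the centred (and, in correlation
#' mode, standardized) traits projected on the eigenvectors; loadings are
#' trait-component correlations. Each component is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix, rows = specimens (rownames must match tree
#'   tips), columns = traits.
#' @param C phylogenetic covariance from [phylo_covariance()], or a
#'   `phylo` tree.
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @param ridge diagonal added to C only if C is numerically singular.
#' @return object of class `ppca`: list with `loadings` (traits x
#'   components), `scores` (specimens x components), `eigenvalues`,
#'   `percent_variance`, `evolutionary_vcv`, `phylo_mean`, `mode`.
#' @export
ppca <- function(X, C, mode = c("correlation", "covariance"),
                 ridge = 1e-10) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (inherits(C, "phylo")) C <- phylo_covariance(C, rownames(X))
  n <- nrow(X); m <- ncol(X)
  if (!all(dim(C) == n)) stopf("C must be %d x %d to match X", n, n)
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    if (!setequal(rownames(X), rownames(C)))
      stopf("row labels of X do not match C")
    C <- C[rownames(X), rownames(X)]
  }
  if (anyNA(X)) stopf("X must have no missing cells")
  if (m > n) warnf("more traits than specimens: evolutionary covariance is rank deficient")
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) {
    Ci <- tryCatch(solve(C + diag(ridge, n)), error = function(e) NULL)
    if (is.null(Ci))
      stopf("C is singular even after ridge %g; check the tree", ridge)
  }
  one <- matrix(1, n, 1)
  a <- as.numeric(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X)
  Xc <- sweep(X, 2, a)
  V <- t(Xc) %*% Ci %*% Xc / (n - 1)
  if (mode == "correlation") {
    sds <- sqrt(diag(V))
    if (any(sds <= 0)) stopf("constant trait column(s): cannot use correlation mode")
    Xc <- sweep(Xc, 2, sds, "/")
    V <- V / (sds %o% sds)
  }
  es <- eigen(V, symmetric = TRUE)
  lambda <- pmax(es$values, 0)
  U <- es$vectors
  # loadings as trait-component correlations: V U / (sd_trait sqrt(lambda));
  # trait sds are 1 in correlation mode
  denom <- sqrt(ifelse(lambda > 0, lambda, 1))
  L <- V %*% U %*% diag(1 / denom, m)
  if (mode == "covariance") L <- L / sqrt(diag(V))
  # orient each component so its dominant trait loads positively
  for (k in seq_len(m)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) {
      L[, k] <- -L[, k]
      U[, k] <- -U[, k]
    }
  }
  S <- Xc %*% U
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(m)))
  dimnames(S) <- list(rownames(X), paste0("PC", seq_len(m)))
  structure(list(loadings = L, scores = S, eigenvalues = lambda,
                 percent_variance = 100 * lambda / sum(lambda),
                 evolutionary_vcv = V, phylo_mean = stats::setNames(a, colnames(X)),
                 mode = mode),
            class = "ppca")
}

#' Cumulative percent variance of the leading components
#'
#' @param result a [ppca()] fit.
#' @param k number of leading components (1 <= k <= number of traits).
#' @return cumulative percent of total variance.
#' @export
variance_explained <- function(result, k) {
  m <- length(result$eigenvalues)
  if (k < 1 || k > m) stopf("k must be between 1 and %d", m)
  sum(result$percent_variance[seq_len(k)])
}

#' @export
print.ppca <- function(x, ...) {
  cat(sprintf("Phylogenetic PCA (%s mode), %d specimens x %d traits\n",
              x$mode, nrow(x$scores), ncol(x$loadings)))
  cat("Percent variance:",
      paste(sprintf("%s %.1f", colnames(x$loadings),
                    x$percent_variance), collapse = ", "), "\n")
  cat("Loadings:\n")
  print(round(x$loadings, 4))
  invisible(x)
}

#' Scatter plot of the first two pPCA score axes
#'
#' @param x a [ppca()] fit.
#' @param groups optional factor (named by specimen or in row order) used
#'   to colour points.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the score matrix.
#' @export
plot.ppca <- function(x, groups = NULL, ...) {
  s <- x$scores
  col <- "black"
  if (!is.null(groups)) {
    g <- if (!is.null(names(groups))) groups[rownames(s)] else groups
    g <- as.factor(g)
    col <- grDevices::hcl.colors(nlevels(g), "Dark 3")[as.integer(g)]
  }
  graphics::plot(s[, 1], s[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", x$percent_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$percent_variance[2]), ...)
  graphics::text(s[, 1], s[, 2], rownames(s), pos = 3, cex = 0.7, col = col)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = grDevices::hcl.colors(nlevels(as.factor(groups)),
                                                 "Dark 3"),
                     pch = 19, bty = "n", cex = 0.8)
  invisible(s)
}
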