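#' Correspondence analysis of a contingency table
#'
#' Standard simple correspondence analysis: the table is divided by its grand
#' total, standardized residuals \eqn{(p_{ij} - r_i c_j) / \sqrt{r_i c_j}}
#' are decomposed by singular value decomposition, and row/column principal
#' coordinates are returned for the leading dimensions. Total inertia equals
#' the Pearson chi-square statistic divided by the grand total. Used to place
#' CSA patterns and follow-up outcome groups in a common 2-D plane.
#'
#' @param tab Non-negative count matrix with at least 2 rows and 2 columns
#'   with positive margins; zero-margin rows/columns are dropped with a
#'   warning.
#' @param n_dim Number of dimensions to retain (default 2).
#' @return A `csa_ca`: list with `row_coords`, `col_coords` (principal
#'   coordinates), `singular_values`, `inertia` (per dimension),
#'   `total_inertia`, and the margins.
#' @examples
#' tab <- matrix(c(0, 13, 5, 19, 1, 3, 1, 0, 0), 3, byrow = TRUE,
#'               dimnames = list(c("P1", "P1plus+2", "P3"),
#'                               c("MCI-DLB", "MCI-AD", "MCI-NC")))
#' correspondence_analysis(tab)
#' @export
correspondence_analysis <- function(tab, n_dim = 2) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("counts must be non-negative", class = "qeegcsa_input_error")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warn("dropping zero-margin rows/columns")
    tab <- tab[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(tab)
    cs <- colSums(tab)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("need >= 2 rows and columns with positive margins",
          class = "qeegcsa_input_error")
  }
  n <- sum(tab)
  P <- tab / n
  r <- rs / n
  c <- cs / n
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)
  k <- min(n_dim, length(sv$d), nrow(tab) - 1, ncol(tab) - 1)
  d <- sv$d[seq_len(k)]
  F <- sweep(sv$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*% diag(d, k)
  G <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(c), "/") %*% diag(d, k)
  dimnames(F) <- list(rownames(tab), paste0("dim", seq_len(k)))
  dimnames(G) <- list(colnames(tab), paste0("dim", seq_len(k)))
  structure(
    list(row_coords = F, col_coords = G,
         singular_values = sv$d[seq_len(min(nrow(tab), ncol(tab)) - 1)],
         inertia = d^2,
         total_inertia = sum(sv$d^2),
         row_mass = r, col_mass = c, n = n),
    class = "csa_ca"
  )
}

#' @export
print.csa_ca <- function(x, ...) {
  cat("<csa_ca> total inertia", signif(x$total_inertia, 5), "\n")
  cat("row principal coordinates:\n")
  print(round(x$row_coords, 4))
  cat("column principal coordinates:\n")
  print(round(x$col_coords, 4))
  invisible(x)
}

#' @method tidy csa_ca
#' @export
tidy.csa_ca <- function(x, ...) {
  rows <- as_tibble(x$row_coords, rownames = "level")
  rows$side <- "row"
  cols <- as_tibble(x$col_coords, rownames = "level")
  cols$side <- "column"
  dplyr::bind_rows(rows, cols)
}

#' @method glance csa_ca
#' @export
glance.csa_ca <- function(x, ...) {
  tibble(
    total_inertia = x$total_inertia,
    inertia_dim1 = x$inertia[1],
    inertia_dim2 = if (length(x$inertia) > 1) x$inertia[2] else NA_real_,
    n = x$n
  )
}

#' @method autoplot csa_ca
#' @export
autoplot.csa_ca <- function(object, ...) {
  d <- tidy(object)
  if (!"dim2" %in% names(d)) d$dim2 <- 0
  ggplot(d, aes(x = .data$dim1, y = .data$dim2,
                colour = .data$side, label = .data$level)) +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_vline(xintercept = 0, colour = "grey80") +
    geom_point() +
    geom_text(vjust = -0.8, show.legend = FALSE) +
    labs(x = "Dimension 1", y = "Dimension 2", colour = NULL,
         title = "Correspondence analysis") +
    theme_minimal()
}
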