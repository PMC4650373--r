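# Independent brute-force oracles used to freeze expected values.

# Upper-tail hypergeometric by exhaustive enumeration of all draws of size n
# from N items of which the first K are marked.
enum_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Conditional two-sample Poisson exact test: group-sum pmfs built by
# explicit convolution of single-library Poisson pmfs, then conditioned on
# the total (no Poisson-additivity or binomial shortcut).
enum_poisson_cond_p <- function(s_a, s_b, n_a, n_b) {
  tot <- s_a + s_b
  mu <- tot / (n_a + n_b)
  single <- dpois(0:tot, mu)
  conv_n <- function(n) {
    pm <- single
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        pm <- stats::convolve(pm, rev(single), type = "open")[1:(tot + 1L)]
      }
    }
    pm
  }
  joint <- conv_n(n_a) * rev(conv_n(n_b))
  joint <- joint / sum(joint)
  sum(joint[joint <= joint[s_a + 1L] * (1 + 1e-10)])
}

# Conditional NB exact test oracle that builds the group-sum pmf by explicit
# convolution of single-library NB pmfs (no size-additivity shortcut).
enum_nb_cond_p <- function(s_a, s_b, n_a, n_b, phi) {
  tot <- s_a + s_b
  mu <- tot / (n_a + n_b)
  r <- 1 / phi
  single <- dnbinom(0:tot, size = r, mu = mu)
  conv_n <- function(n) {
    pm <- single
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        pm <- stats::convolve(pm, rev(single), type = "open")[1:(tot + 1L)]
      }
    }
    pm
  }
  pa <- conv_n(n_a)
  pb <- conv_n(n_b)
  joint <- pa * rev(pb)          # P(A = a) * P(B = tot - a)
  joint <- joint / sum(joint)
  sum(joint[joint <= joint[s_a + 1L] * (1 + 1e-10)])
}

# Small deterministic long-format fold-change table.
make_fc <- function(cells, n_reps = 3) {
  # cells: tibble tf, target, fold (exact per replicate)
  tidyr::expand_grid(cells, replicate = seq_len(n_reps)) |>
    dplyr::transmute(target, tf, replicate, fold_change = fold)
}

# Tiny deterministic expression panel.
make_panel <- function(focal, others, ids = NULL, is_tf = FALSE, n_other = 3) {
  n <- length(focal)
  ids <- ids %||% sprintf("g%02d", seq_len(n))
  tpm <- cbind(focal, matrix(rep(others, n_other), nrow = n))
  rownames(tpm) <- ids
  colnames(tpm) <- c("focal", paste0("s", seq_len(n_other)))
  meta <- tibble::tibble(id = ids, symbol = toupper(ids),
                         is_tf = rep_len(is_tf, n))
  expression_panel(tpm, "focal", meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
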