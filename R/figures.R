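#' Data behind the theory's standard figures
#'
#' Computes, as tidy tables, the curves that illustrate the theory:
#' \describe{
#'   \item{fig1}{steady-state concentration versus nucleation capacity,
#'     exact law and its small-`N` linearization, generic cell. Columns
#'     `N_over_nu`, `N`, `c_exact_uM`, `c_linear_uM`.}
#'   \item{fig2}{planar density profiles `m(x)` for `N` in \{100, 1000,
#'     2000\}, generic cell. Columns `x_um`, `m_N100`, `m_N1000`, `m_N2000`.}
#'   \item{fig3}{optimal nucleation capacity versus distance. Columns
#'     `x_um`, `x_over_xi`, `N_c`.}
#'   \item{fig4}{organelle capture `P(x)` for `(N, d_o)` in
#'     \{100, 2000\} x \{1, 2\} um. Columns `x_um`, `P_N100_do1`,
#'     `P_N100_do2`, `P_N2000_do1`, `P_N2000_do2`.}
#'   \item{fig5}{total pronucleus capture `P_t(N_m)` in the *Beroe* egg for
#'     `N_f` in \{1e2, 1e5, 3e5, 1e6\}. Columns `N_m`, `Pt_Nf1e2`,
#'     `Pt_Nf1e5`, `Pt_Nf3e5`, `Pt_Nf1e6`.}
#'   \item{fig6}{per-aster capture `P_a(N_a)` under polyspermy, `n` in
#'     \{1, 3, 6, 9\}, one block per `N_f` in \{1e5, 3e5\}. Columns `N_f`,
#'     `N_a`, `Pa_n1`, `Pa_n3`, `Pa_n6`, `Pa_n9`.}
#' }
#' Profile grids are log-spaced (the planar density diverges at small `x`).
#'
#' @param figure One of `"fig1"` ... `"fig6"`.
#' @param points Grid points per curve (per decade for log grids of capacity
#'   sweeps, total otherwise). Defaults give smooth curves in seconds.
#' @return A `data.frame`, one row per grid point, one column per curve.
#' @export
figure_data <- function(figure = c("fig1", "fig2", "fig3", "fig4",
                                   "fig5", "fig6"),
                        points = NULL) {
  figure <- match.arg(figure)
  generic <- cell_preset("generic")
  switch(figure,
    fig1 = {
      np <- points %||% 201L
      nu <- derived_constants(generic)$nu
      # abscissa extended well beyond realistic N (the linear law's c would
      # cross zero near N/nu = 0.85 for the generic cell, so stop at 0.8)
      N_over_nu <- seq(0, 0.8, length.out = np)
      N <- N_over_nu * nu
      data.frame(
        N_over_nu = N_over_nu, N = N,
        c_exact_uM = vapply(N, function(n) steady_c_exact(n, generic)$c,
                            numeric(1)),
        c_linear_uM = vapply(N, function(n) steady_c_linear(n, generic)$c,
                             numeric(1)))
    },
    fig2 = {
      np <- points %||% 200L
      x <- exp(seq(log(0.5), log(100), length.out = np))
      out <- data.frame(x_um = x)
      for (N in c(100, 1000, 2000)) {
        out[[paste0("m_N", N)]] <- planar_density(x, N, generic)
      }
      out
    },
    fig3 = {
      np <- points %||% 200L
      xi <- derived_constants(generic)$xi
      x <- exp(seq(log(1), log(100), length.out = np))
      data.frame(x_um = x, x_over_xi = x / xi,
                 N_c = optimal_nucleation(x, generic))
    },
    fig4 = {
      np <- points %||% 200L
      x <- exp(seq(log(0.5), log(100), length.out = np))
      out <- data.frame(x_um = x)
      for (N in c(100, 2000)) for (d_o in c(1, 2)) {
        out[[sprintf("P_N%d_do%d", N, d_o)]] <-
          suppressWarnings(capture_probability(x, N, d_o, generic))
      }
      out
    },
    fig5 = {
      per_decade <- points %||% 10L
      scen <- egg_scenario()
      N_m <- 10^seq(2, 7, by = 1 / per_decade)
      out <- data.frame(N_m = N_m)
      for (N_f in c(1e2, 1e5, 3e5, 1e6)) {
        col <- paste0("Pt_Nf", format(N_f, scientific = TRUE, digits = 1))
        col <- gsub("[+]0?", "", col)
        out[[col]] <- vapply(N_m, function(nm) {
          suppressWarnings(total_capture(nm, N_f, scen))$P
        }, numeric(1))
      }
      out
    },
    fig6 = {
      per_decade <- points %||% 10L
      scen <- egg_scenario()
      N_a <- 10^seq(2, 7, by = 1 / per_decade)
      blocks <- lapply(c(1e5, 3e5), function(N_f) {
        out <- data.frame(N_f = N_f, N_a = N_a)
        for (n in c(1, 3, 6, 9)) {
          out[[paste0("Pa_n", n)]] <- vapply(N_a, function(na) {
            suppressWarnings(per_aster_capture(na, n, N_f, scen))$P
          }, numeric(1))
        }
        out
      })
      do.call(rbind, blocks)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a figure table as a reproducible CSV
#'
#' Numeric columns are formatted at full double precision (`%.17g`), so a
#' rerun with the same inputs is byte-identical and downstream plotting is
#' bit-stable.
#'
#' @param df A data frame (e.g. from [figure_data()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_figure_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
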