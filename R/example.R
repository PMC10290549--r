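#' The packaged Nephrin/Nck/NWASP multivalent clustering model
#'
#' A canonical mixed-valence membrane-signaling system: Nephrin carries
#' three phosphotyrosines (`y1`-`y3`), each able to bind the single SH2
#' domain of Nck; Nck additionally carries three SH3 domains
#' (`sh3a`-`sh3c`), each able to bind any of the six proline-rich motifs
#' (`p1`-`p6`) of NWASP. Every pairwise site combination is one reversible
#' binding rule (3 + 18 = 21 rules), all sharing the same on/off rate
#' constants within their interaction class.
#'
#' Rate constants and copy numbers are documented placeholder parameters:
#' the copy numbers (180/540/270, about 990 molecules) are
#' site-stoichiometric (540 phosphotyrosines vs 540 SH2 domains; 1620 SH3
#' domains vs 1620 PRMs), and the two affinity presets sit far on either
#' side of the clustering threshold, so the occupancy distribution is
#' monomer-dominated and unimodal at `"low"` affinity and bimodal with a
#' supply-limited giant cluster at `"high"` affinity.
#'
#' @param affinity `"high"` (kon = 0.1, koff = 0.01; clustered regime) or
#'   `"low"` (kon = 1e-5, koff = 1; dispersed regime), or `"custom"` to use
#'   `kon`/`koff` as given.
#' @param kon,koff stochastic rate constants used when
#'   `affinity = "custom"`.
#' @param n_nephrin,n_nck,n_nwasp seed copy numbers.
#' @param t_end,n_steps,n_runs,seed simulation parameters.
#' @return A [bngl_model()].
#' @export
#' @examples
#' m <- nephrin_nck_nwasp_model(affinity = "low", n_runs = 2)
#' print(m)
nephrin_nck_nwasp_model <- function(affinity = c("high", "low", "custom"),
                                    kon = NULL, koff = NULL,
                                    n_nephrin = 180L, n_nck = 540L,
                                    n_nwasp = 270L,
                                    t_end = 10, n_steps = 20,
                                    n_runs = 10L, seed = 1L) {
  affinity <- match.arg(affinity)
  rates <- switch(affinity,
                  high = c(0.1, 0.01),
                  low = c(1e-5, 1),
                  custom = c(kon, koff))
  if (length(rates) != 2L || anyNA(rates))
    stop("custom affinity requires kon and koff")
  mt <- list(Nephrin = c("y1", "y2", "y3"),
             Nck = c("sh2", "sh3a", "sh3b", "sh3c"),
             NWASP = paste0("p", 1:6))
  ysites <- mt$Nephrin
  sh3 <- c("sh3a", "sh3b", "sh3c")
  prm <- mt$NWASP
  rules <- rbind(
    binding_rule("Nephrin", ysites, "Nck", "sh2", rates[1L], rates[2L],
                 name = paste0("neph_", ysites, "_nck_sh2")),
    binding_rule("Nck", rep(sh3, each = 6L), "NWASP", rep(prm, 3L),
                 rates[1L], rates[2L],
                 name = paste0("nck_", rep(sh3, each = 6L),
                               "_nwasp_", rep(prm, 3L))))
  obs <- data.frame(
    name = c("Nephrin_free", "Nck_free", "NWASP_free", "clusters"),
    kind = c("free_molecule", "free_molecule", "free_molecule",
             "total_clusters"),
    target = c("Nephrin", "Nck", "NWASP", ""),
    stringsAsFactors = FALSE)
  bngl_model(mt,
             c(Nephrin = n_nephrin, Nck = n_nck, NWASP = n_nwasp),
             rules, observables = obs,
             sim_params = list(t_end = t_end, n_steps = n_steps,
                               n_runs = n_runs, seed = seed))
}

#' Path to the packaged example model file
#'
#' The BNGL-dialect file equivalent to [nephrin_nck_nwasp_model()] with
#' default (high-affinity) parameters, for exercising the file-based
#' workflow and the command-line tools.
#'
#' @return Path to the installed `.bngl` file.
#' @export
example_model_path <- function() {
  system.file("extdata", "nephrin_nck_nwasp.bngl", package = "nfcluster",
              mustWork = TRUE)
}
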