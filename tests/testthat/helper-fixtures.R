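# Shared fixtures: everything is generated in code at test time.

CHOWT_RULES <- c("C1GALT1", "ST3GAL_a", "ST6GALNAC_a", "ST6GALNAC_b",
                 "ST6GALNAC_c")

chowt_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_network(default_ruleset(), CHOWT_RULES)
    cache
  }
})

# the three structures of the wild-type CHO profile
CHOWT_STRUCTURES <- c("Galβ1-3(NeuAcα2-6)GalNAcol",
                      "NeuAcα2-3Galβ1-3GalNAcol",
                      "NeuAcα2-3Galβ1-3(NeuAcα2-6)GalNAcol")

# closed-form solution of the irreversible Michaelis-Menten batch reactor
# dS/dt = -B S / (Km + S): solves Km log(S0/S) + (S0 - S) = B t for S.
mm_batch_substrate <- function(S0, Km, B, t) {
  g <- function(S) Km * log(S0 / S) + (S0 - S) - B * t
  if (g(S0) > 0) return(S0)
  stats::uniroot(g, lower = S0 * 1e-300, upper = S0, tol = 1e-14)$root
}
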