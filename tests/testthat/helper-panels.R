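# small in-code fixtures shared across tests

# case panel on the fine scheme with counts only in named classes
tiny_cases <- function(counts, region = "A", year = 2000L) {
  scheme <- fine_age_scheme()
  data.frame(region = region, year = year,
             age_class = names(counts),
             count = as.numeric(counts),
             stringsAsFactors = FALSE)
}

# uniform population panel on the coarse scheme
tiny_pop <- function(per_class = 10000, region = "A", year = 2000L,
                     scheme = coarse_age_scheme()) {
  expand.grid(region = region, year = year, age_class = scheme$label,
              stringsAsFactors = FALSE) |>
    transform(population = per_class)
}

uniform_standard <- function(scheme = coarse_age_scheme()) {
  data.frame(age_class = scheme$label,
             proportion = rep(1 / nrow(scheme), nrow(scheme)))
}

lattice47 <- function() {
  ids <- sprintf("R%02d", 1:47)
  build_adjacency(kdpanel:::.lattice_edges(47, ids), ids)
}

# AR(1) panel generator used for estimator unit tests (distinct from the
# package's scenario generator, so the two can cross-validate)
gen_ar1_panel <- function(n_regions, n_years, alpha, beta, phi,
                          sigma_nu, sigma_eta, seed) {
  set.seed(seed)
  regions <- sprintf("r%02d", seq_len(n_regions))
  x <- matrix(rnorm(n_regions * n_years), n_regions)
  nu <- rnorm(n_regions, sd = sigma_nu)
  eps <- t(sapply(seq_len(n_regions), function(i) {
    e <- numeric(n_years)
    e[1] <- rnorm(1, sd = sigma_eta / sqrt(max(1 - phi^2, 1e-12)))
    for (t in seq_len(n_years - 1)) e[t + 1] <- phi * e[t] + rnorm(1, sd = sigma_eta)
    e
  }))
  data.frame(region = rep(regions, n_years),
             year = rep(2000L + seq_len(n_years) - 1L, each = n_regions),
             x = as.vector(x),
             y = alpha + beta * as.vector(x) + rep(nu, n_years) + as.vector(eps),
             stringsAsFactors = FALSE)
}
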