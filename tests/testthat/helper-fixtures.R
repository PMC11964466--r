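# Shared fixtures, built in code.

km <- 1000  # metres per kilometre

square_window <- function(side_km, origin_km = 0) {
  rect_window(origin_km * km, (origin_km + side_km) * km,
              origin_km * km, (origin_km + side_km) * km)
}

# the two-cluster recovery scenario: two Thomas clusters of sigma 15 km in a
# 300 km square with a weak uniform background (disc-mean contrast ~ 23x)
recovery_sim <- function(seed) {
  simulate_sites(square_window(300),
                 centres = rbind(c(75, 75), c(225, 225)) * km,
                 mu = 200, sigma_km = 15, background = 1.5e-3, seed = seed)
}

# write a site table CSV and return its path
write_site_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# expand the packaged attribution census into one record per assemblage
census_sites <- function() {
  census <- utils::read.csv(system.file("extdata",
                                        "published_attribution_census.csv",
                                        package = "colognepop"))
  n <- sum(census$n_assemblages)
  tibble::tibble(
    id = sprintf("a%04d", seq_len(n)),
    x = seq_len(n), y = seq_len(n), region = "all",
    attributions = rep(census$flag, census$n_assemblages),
    evidence = "excavation"
  )
}

# independent shoelace evaluation used as an area oracle in tests
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:length(x), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
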