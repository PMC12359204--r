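# One-off generator for the shipped coarse torsion tables (inst/extdata).
# Smooth analytic basin models on a 15-degree periodic grid; energies in
# arbitrary units relative to the global minimum, capped at 8; cells above
# 6.5 are masked as disallowed. Dhb = Dha landscape with its sp3-clashing
# basins removed and masked (gamma-methyl / backbone steric exclusion), so
# Dhb's allowed set is a strict subset of Dha's.
# standalone: run from the package root with Rscript data-raw/make_tables.R

grid <- seq(-180, 165, by = 15)

wrapdiff <- function(a, b) ((a - b + 180) %% 360) - 180

basin_energy <- function(phi, psi, basins, cap = 8, kT = 1.2) {
  dens <- 0
  for (b in basins) {
    d2 <- (wrapdiff(phi, b$phi) / b$sphi)^2 + (wrapdiff(psi, b$psi) / b$spsi)^2
    dens <- dens + b$w * exp(-d2 / 2)
  }
  -kT * log(dens + 1e-8)
}

make_table <- function(code, basins, extra_mask = NULL, mask_at = 6.5) {
  E <- matrix(0, length(grid), length(grid))
  for (i in seq_along(grid)) for (j in seq_along(grid))
    E[i, j] <- basin_energy(grid[i], grid[j], basins)
  E <- E - min(E)
  E <- pmin(E, 8)
  M <- E >= mask_at
  if (!is.null(extra_mask))
    for (i in seq_along(grid)) for (j in seq_along(grid))
      if (extra_mask(grid[i], grid[j])) { M[i, j] <- TRUE }
  E[M] <- 8
  list(code = code, spacing = 15, phi = grid, psi = grid,
       energy = round(E, 4), mask = M)
}

general <- make_table("GENERAL", list(
  list(phi = -63, psi = -43, sphi = 30, spsi = 30, w = 1.0),    # alpha
  list(phi = -120, psi = 135, sphi = 45, spsi = 45, w = 1.0),   # beta
  list(phi = -65, psi = 150, sphi = 35, spsi = 30, w = 0.5),    # ppII
  list(phi = 57, psi = 47, sphi = 20, spsi = 20, w = 0.08)))    # left alpha

glycine <- make_table("GLY", list(
  list(phi = -80, psi = 80, sphi = 40, spsi = 40, w = 1.0),
  list(phi = 80, psi = -80, sphi = 40, spsi = 40, w = 1.0),
  list(phi = -63, psi = -43, sphi = 30, spsi = 30, w = 0.7),
  list(phi = 63, psi = 43, sphi = 30, spsi = 30, w = 0.7),
  list(phi = 180, psi = 180, sphi = 50, spsi = 50, w = 0.5)))

proline <- make_table("PRO", list(
  list(phi = -63, psi = 150, sphi = 15, spsi = 30, w = 1.0),
  list(phi = -63, psi = -35, sphi = 15, spsi = 30, w = 0.8)))

# sp2 alpha carbon: (phi,psi) <-> (-phi,-psi) symmetric bands
dha_basins <- list(
  list(phi = -60, psi = 130, sphi = 35, spsi = 35, w = 1.0),
  list(phi = 60, psi = -130, sphi = 35, spsi = 35, w = 1.0),
  list(phi = -55, psi = -45, sphi = 30, spsi = 30, w = 0.8),
  list(phi = 55, psi = 45, sphi = 30, spsi = 30, w = 0.8))
dha <- make_table("DHA", dha_basins)

# Dhb: the Z gamma-methyl clashes with the backbone in the helical-like
# basins; those cells are excluded outright
dhb_steric <- function(phi, psi)
  (abs(wrapdiff(phi, -55)) <= 45 && abs(wrapdiff(psi, -45)) <= 45) ||
  (abs(wrapdiff(phi, 55)) <= 45 && abs(wrapdiff(psi, 45)) <= 45)
dhb <- make_table("DHB", dha_basins, extra_mask = dhb_steric)

write_one <- function(tab, path) {
  con <- file(path, "w")
  writeLines(c("# lanthifold torsion table",
               paste("code", tab$code),
               paste("spacing", format(tab$spacing)),
               "phi\tpsi\tenergy\tmask"), con)
  for (i in seq_along(tab$phi))
    for (j in seq_along(tab$psi))
      writeLines(sprintf("%g\t%g\t%.4f\t%d", tab$phi[[i]], tab$psi[[j]],
                         tab$energy[i, j], as.integer(tab$mask[i, j])), con)
  close(con)
}

dir.create("inst/extdata/torsion_tables", recursive = TRUE, showWarnings = FALSE)
write_one(general, "inst/extdata/torsion_tables/general.tsv")
write_one(glycine, "inst/extdata/torsion_tables/glycine.tsv")
write_one(proline, "inst/extdata/torsion_tables/proline.tsv")
write_one(dha, "inst/extdata/torsion_tables/dha.tsv")
write_one(dhb, "inst/extdata/torsion_tables/dhb.tsv")

# sanity: Dhb allowed strictly inside Dha allowed
stopifnot(all(!dhb$mask == (!dhb$mask & !dha$mask)), sum(!dhb$mask) < sum(!dha$mask))
cat("allowed cells:", sum(!general$mask), sum(!glycine$mask), sum(!proline$mask),
    sum(!dha$mask), sum(!dhb$mask), "\n")
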