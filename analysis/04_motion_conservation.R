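#!/usr/bin/env Rscript
# The core analysis: essential-dynamics PCA of the 128 chain-A Calphas for
# every system, directional similarity sigma_mn of its first two principal
# components against the wild-type reference, Sigma_C / Sigma_U
# classification, and the per-residue Sigma_C profile. The generator
# planted the truth: mod-ident must classify conserved, mod-swap
# unconserved; mod-rand shares no structure with the reference, so both
# sums land near 1 and the label is effectively a coin toss; mod-rot45
# sits between the regimes.

library(motioncons)

cfg <- yaml::read_yaml("scratch/demo/config.yaml")
dir.create("results", showWarnings = FALSE)

modes_of <- function(s) {
  str <- read_structure(file.path("scratch/demo", s$structure))
  traj <- read_trajectory(file.path("scratch/demo", s$trajectory), str)
  sel <- select_atoms(str, cfg$selections$thumb_ca)
  cov <- build_covariance(traj, sel, superpose = TRUE)
  list(modes = principal_modes(cov, n_modes = 2), str = str,
       eigenvalues = principal_modes(cov, n_modes = 6)$values)
}

ref_i <- which(vapply(cfg$systems, function(s)
  s$name == cfg$reference && is.null(s$isomer), logical(1)))
ref <- modes_of(cfg$systems[[ref_i]])
cat(sprintf("reference eigenvalue spectrum (nm^2): %s ...\n",
            paste(signif(ref$eigenvalues, 3), collapse = ", ")))

rows <- list(); perres <- list()
for (s in cfg$systems) {
  tag <- if (is.null(s$isomer)) s$name else paste0(s$name, "_", s$isomer)
  m <- if (tag == "wt") ref else modes_of(s)
  cons <- conservation_classify(m$modes, ref$modes,
                                sign_policy = cfg$sign_policy)
  rows[[tag]] <- data.frame(
    system = tag,
    sigma_11 = cons$sigma[1, 1], sigma_12 = cons$sigma[1, 2],
    sigma_21 = cons$sigma[2, 1], sigma_22 = cons$sigma[2, 2],
    sigma_c = cons$sigma_c, sigma_u = cons$sigma_u, label = cons$label)
  perres[[tag]] <- per_residue_conservation(cons, m$str)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/conservation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nconservation classification vs wt (results/conservation.tsv):\n")
print(tab, row.names = FALSE, digits = 3)

# per-residue profile for the swap systems: conservation loss is global
# when the leading modes trade places, so the profile should be depressed
# across the whole chain rather than at one spot
pr <- perres[["mod-swap_S"]]
write.table(pr, "results/perres_sigma_c_mod-swap_S.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("\nmod-swap_S per-residue Sigma_C: mean %.3f (= Sigma_C %.3f), range [%.2f, %.2f]\n",
            mean(pr$sigma_c), tab["mod-swap_S", "sigma_c"],
            min(pr$sigma_c), max(pr$sigma_c)))
pi_ <- perres[["mod-ident_S"]]
write.table(pi_, "results/perres_sigma_c_mod-ident_S.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("mod-ident_S per-residue Sigma_C: mean %.3f, range [%.2f, %.2f]\n",
            mean(pi_$sigma_c), min(pi_$sigma_c), max(pi_$sigma_c)))
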