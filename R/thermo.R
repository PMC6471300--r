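#' Assemble a Gibbs free energy from enthalpy and entropy terms
#'
#' `dG = dH - TdS`, with both terms in kcal/mol (`TdS` already includes
#' the temperature factor).
#'
#' @param dH enthalpy change, kcal/mol.
#' @param TdS entropy term T * dS, kcal/mol.
#' @return dG in kcal/mol.
#' @export
gibbs_combine <- function(dH, TdS) dH - TdS

#' Affinity fold change between two binding free energies
#'
#' `exp((dG_weak - dG_strong) / (R T))`: the ratio of association
#' constants of the stronger over the weaker binder; >= 1 whenever
#' `dG_strong <= dG_weak`.
#'
#' @param dG_weak,dG_strong binding free energies, kcal/mol (more
#'   negative = stronger).
#' @param temperature kelvin. Default 298.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(dG_weak, dG_strong, temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  exp((dG_weak - dG_strong) / (KB_KCAL * temperature))
}

#' Configurational entropy by the PCA-histogram method
#'
#' Frames are superposed onto the first frame (removing global rigid
#' motion), the flattened Cartesian deviations are decomposed by PCA,
#' each retained component is histogrammed independently, and the
#' discrete Shannon entropy is summed over components:
#' `S = -kB sum_c sum_bins p ln p`. The result is bin-width dependent and
#' comparable only at fixed binning, which is recorded in the output.
#'
#' @param traj a [trajectory()] (or a frames x 3N coordinate matrix) of
#'   the selection of interest.
#' @param n_components number of principal components retained. Default
#'   10.
#' @param n_bins histogram bins per component. Default 30.
#' @param temperature kelvin, used for the reported `TdS`. Default 298.
#' @param align superpose frames first. Default TRUE.
#' @return List with `S` (kcal/(mol K)), `TdS` (kcal/mol),
#'   `per_component` entropies, and the binning record.
#' @export
pca_histogram_entropy <- function(traj, n_components = 10, n_bins = 30,
                                  temperature = 298, align = TRUE) {
  xyz <- if (inherits(traj, "trajectory")) traj$xyz else as.matrix(traj)
  nf <- nrow(xyz)
  if (nf < 2L) stop("need at least 2 frames")
  if (n_components < 1L || n_bins < 2L)
    stop("need n_components >= 1 and n_bins >= 2")
  if (nf < n_components)
    stop(sprintf("fewer frames (%d) than components (%d)", nf, n_components))
  if (align) {
    ref <- matrix(xyz[1L, ], ncol = 3L, byrow = TRUE)
    for (f in 2:nf) {
      crd <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      xyz[f, ] <- as.vector(t(apply_transform(crd, kabsch_fit(crd, ref))))
    }
  }
  if (max(apply(xyz, 2L, sd)) < 1e-12) {
    # a single microstate: no configurational entropy
    return(list(S = 0, TdS = 0, per_component = numeric(0),
                n_components = n_components, n_bins = n_bins,
                temperature = temperature))
  }
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  per <- vapply(seq_len(k), function(j) {
    x <- pc$x[, j]
    if (sd(x) < 1e-12) return(0)
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    br[1] <- br[1] - 1e-9; br[n_bins + 1L] <- br[n_bins + 1L] + 1e-9
    p <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins) / length(x)
    p <- p[p > 0]
    -KB_KCAL * sum(p * log(p))
  }, numeric(1))
  S <- sum(per)
  list(S = S, TdS = temperature * S, per_component = per,
       n_components = k, n_bins = n_bins, temperature = temperature)
}

#' Binding entropy difference
#'
#' `dS = S_complex - S_receptor - S_ligand`; all inputs must share the
#' same temperature and binning convention.
#'
#' @param S_complex,S_receptor,S_ligand entropies (any consistent unit).
#' @return The difference, same unit.
#' @export
binding_entropy_delta <- function(S_complex, S_receptor, S_ligand) {
  S_complex - S_receptor - S_ligand
}

#' Read a binding-thermodynamics table
#'
#' TSV with columns `ligand`, `orientation`, `dG`, `dH`, `TdS`
#' (kcal/mol; optional `*_se` uncertainty columns are kept).
#'
#' @param path TSV path. Default: the table of lipid-transfer-protein
#'   ligand estimates shipped with the package.
#' @return Data frame.
#' @export
read_thermo_table <- function(path = system.file("extdata",
                                                 "ltp_binding_thermo.tsv",
                                                 package = "tunnelscape")) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("ligand", "orientation", "dG", "dH", "TdS")
  if (!all(need %in% names(df)))
    stop("thermo table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Check thermodynamic consistency of a binding table
#'
#' Recomputes `dG` from `dH` and `TdS` via [gibbs_combine()] and flags
#' rows where the printed `dG` disagrees beyond `tol` — typically
#' transcription problems such as a dropped minus sign on an entropy
#' term.
#'
#' @param table data frame from [read_thermo_table()].
#' @param tol agreement tolerance, kcal/mol. Default 0.01 (rounding of
#'   printed values).
#' @return The table with added columns `dG_computed`, `residual`, and
#'   logical `consistent`.
#' @export
check_thermo_table <- function(table, tol = 0.01) {
  table$dG_computed <- gibbs_combine(table$dH, table$TdS)
  table$residual <- table$dG - table$dG_computed
  table$consistent <- abs(table$residual) <= tol
  table
}
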