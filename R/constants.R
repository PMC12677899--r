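# Physical constants pinned for bit-reproducible output.

#' Physical constants used throughout condx
#'
#' Boltzmann constant in kJ/mol/K (`kB`), elementary charge in coulomb (`e`),
#' vacuum permittivity in F/m (`eps0`), Avogadro's number (`N_A`), the Debye in
#' C*m (`debye`), and the factor converting (g/mol)/nm^3 to mg/mL
#' (`gmol_nm3_to_mgml`).
#'
#' @format Named list of scalars.
#' @export
condx_constants <- list(
  kB        = 0.00831446,          # kJ/mol/K
  kB_SI     = 1.380649e-23,        # J/K
  e         = 1.602176634e-19,     # C
  eps0      = 8.8541878128e-12,    # F/m
  N_A       = 6.02214076e23,       # 1/mol
  debye     = 3.33564e-30,         # C*m
  kcal      = 4.184,               # kJ per kcal
  gmol_nm3_to_mgml = 1e24 / 6.02214076e23  # (g/mol)/nm^3 -> mg/mL
)

#' Default simulation temperature (K)
#' @keywords internal
DEFAULT_T <- 298
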