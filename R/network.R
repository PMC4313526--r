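#' Species and reaction labels of the macroreaction scheme
#'
#' The model tracks 11 extracellular metabolites plus the viable (\code{X})
#' and dead (\code{Xd}) cell concentrations.
#'
#' @name mabkin-species
#' @keywords internal
NULL

SPECIES <- c("GLC", "GLN", "GLU", "ASN", "ASP",
             "LAC", "ALA", "PRO", "MAb", "BM", "NH3")
CELLS <- c("X", "Xd")
STATES <- c(SPECIES, CELLS)
REACTIONS <- paste0("r", 1:9)

#' Build the macroreaction stoichiometric network
#'
#' Constructs the signed 11 x 9 stoichiometric matrix \eqn{K} linking the
#' nine macroreactions of the antibody-producing hybridoma culture to the
#' balance equations of the 11 extracellular metabolites (glucose,
#' glutamine, glutamate, asparagine, aspartate, lactate, alanine, proline,
#' monoclonal antibody, biomass, ammonia).  Entries are negative for a
#' reaction's substrates and positive for its products; biomass and
#' antibody synthesis (reactions 7 and 8) consume small stoichiometric
#' amounts of several amino acids.
#'
#' @return An object of class \code{reaction_network}: a list with
#'   \code{species} (character, length 11), \code{reactions} (character,
#'   length 9) and \code{K} (numeric 11 x 9 matrix, dimnames set).
#' @examples
#' net <- build_network()
#' net$K["GLC", "r1"]   # -1: glucose consumed by the lactate reaction
#' net$K["LAC", "r1"]   # +2: two lactate produced per glucose
#' @export
build_network <- function() {
  K <- matrix(0, nrow = 11, ncol = 9,
              dimnames = list(SPECIES, REACTIONS))
  # r1: GLC -> 2 LAC
  K["GLC", 1] <- -1;    K["LAC", 1] <- 2
  # r2: GLC + 2 GLU -> 2 ALA + 2 LAC
  K["GLC", 2] <- -1;    K["GLU", 2] <- -2
  K["ALA", 2] <- 2;     K["LAC", 2] <- 2
  # r3: GLC + 2 GLU -> 2 ASP + 2 LAC
  K["GLC", 3] <- -1;    K["GLU", 3] <- -2
  K["ASP", 3] <- 2;     K["LAC", 3] <- 2
  # r4: GLU -> PRO
  K["GLU", 4] <- -1;    K["PRO", 4] <- 1
  # r5: ASN -> ASP + NH3
  K["ASN", 5] <- -1;    K["ASP", 5] <- 1;  K["NH3", 5] <- 1
  # r6: GLN + ASP -> ASN + GLU
  K["GLN", 6] <- -1;    K["ASP", 6] <- -1
  K["ASN", 6] <- 1;     K["GLU", 6] <- 1
  # r7: 0.0508 GLC + 0.0577 GLN + 0.0133 ALA + 0.006 ASN
  #     + 0.0201 ASP + 0.0016 GLU + 0.081 PRO -> BM
  K["GLC", 7] <- -0.0508; K["GLN", 7] <- -0.0577
  K["ALA", 7] <- -0.0133; K["ASN", 7] <- -0.006
  K["ASP", 7] <- -0.0201; K["GLU", 7] <- -0.0016
  K["PRO", 7] <- -0.081;  K["BM", 7]  <- 1
  # r8: 0.0104 GLN + 0.011 ALA + 0.072 ASN + 0.082 ASP
  #     + 0.0107 GLU + 0.0148 PRO -> MAb
  K["GLN", 8] <- -0.0104; K["ALA", 8] <- -0.011
  K["ASN", 8] <- -0.072;  K["ASP", 8] <- -0.082
  K["GLU", 8] <- -0.0107; K["PRO", 8] <- -0.0148
  K["MAb", 8] <- 1
  # r9: GLN -> GLU + NH3
  K["GLN", 9] <- -1;    K["GLU", 9] <- 1;  K["NH3", 9] <- 1

  structure(list(species = SPECIES, reactions = REACTIONS, K = K),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Macroreaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  print(x$K)
  invisible(x)
}

# substrate -> half-saturation-constant map of the saturable kinetics:
# reaction i runs at phi_i* X prod_j Sj/(KS[j,i] + Sj) over its substrates.
# Reactions 7-9 are deliberately limited by glutamine only.
RATE_SUBSTRATES <- list(
  r1 = c(GLC = "KS1_1"),
  r2 = c(GLC = "KS1_2", GLU = "KS3_2"),
  r3 = c(GLC = "KS1_3", GLU = "KS3_3"),
  r4 = c(GLU = "KS3_4"),
  r5 = c(ASN = "KS4_5"),
  r6 = c(GLN = "KS2_6", ASP = "KS5_6"),
  r7 = c(GLN = "KS2_7"),
  r8 = c(GLN = "KS2_8"),
  r9 = c(GLN = "KS2_9")
)

KS_NAMES <- unname(unlist(RATE_SUBSTRATES))
PHI_NAMES <- paste0("phi", 1:9)
PARAM_NAMES <- c(PHI_NAMES, KS_NAMES, "mu", "kd")
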