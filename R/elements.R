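# Element data: atomic numbers, masses (amu), covalent radii (Angstrom,
# Cordero et al. values), and the default valency table used for implicit-H
# assignment. The valency table follows the SMILES "organic subset"
# convention (B 3, C 4, N 3, O 2, P 3, S 2, halogens 1) and is configurable:
# pass a modified table to the functions that take `valency`.

.element_table <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
             "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Se", "Br", "I"),
  number = c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L,
             14L, 15L, 16L, 17L, 18L, 19L, 20L, 34L, 35L, 53L),
  mass = c(1.008, 4.0026, 10.811, 12.011, 14.007, 15.999, 18.998, 20.180,
           22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948,
           39.098, 40.078, 78.971, 79.904, 126.904),
  radius = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58, 1.66, 1.41,
             1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76, 1.20, 1.20,
             1.39),
  stringsAsFactors = FALSE
)

#' Default maximum-valency table
#'
#' Named integer vector mapping element symbols to the maximum valency used
#' for implicit-hydrogen assignment and for the element-labelling step of
#' graph enumeration. Defaults follow the SMILES organic-subset convention.
#' A hypervalent variant (P = 5, S = 6) can be requested via
#' `default_valency(hypervalent = TRUE)`.
#'
#' @param hypervalent logical; allow hypervalent P and S.
#' @return named integer vector.
#' @export
default_valency <- function(hypervalent = FALSE) {
  v <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
         F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = 2L, Si = 4L, H = 1L)
  if (hypervalent) {
    v["P"] <- 5L
    v["S"] <- 6L
  }
  v
}

#' Elements of the SMILES organic subset
#' @return character vector of element symbols.
#' @export
organic_subset <- function() {
  c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
}

element_number <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("unknown element(s): ",
                     paste(unique(symbol[is.na(i)]), collapse = ", "))
  .element_table$number[i]
}

element_symbol <- function(number) {
  i <- match(number, .element_table$number)
  if (anyNA(i)) stop("unknown atomic number(s): ",
                     paste(unique(number[is.na(i)]), collapse = ", "))
  .element_table$symbol[i]
}

element_mass <- function(symbol) {
  .element_table$mass[match(symbol, .element_table$symbol)]
}

#' Covalent radius lookup
#' @param symbol character vector of element symbols.
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(symbol) {
  .element_table$radius[match(symbol, .element_table$symbol)]
}

# Charge-adjusted maximum valency. Standard rules: group 13 (B) gains a bond
# per negative charge; C loses a bond per unit of |charge|; N/P/O/S shift by
# +charge (N+ 4, N- 2, O- 1, O+ 3); halogens shift by +charge, floored at 0.
adjusted_valency <- function(symbol, charge, valency = default_valency()) {
  base <- unname(valency[symbol])
  if (anyNA(base)) {
    bad <- unique(symbol[is.na(base)])
    stop("no valency entry for element(s): ", paste(bad, collapse = ", "))
  }
  adj <- ifelse(symbol == "B", base - charge,
         ifelse(symbol %in% c("C", "Si"), base - abs(charge),
                base + charge))
  pmax(adj, 0L)
}
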