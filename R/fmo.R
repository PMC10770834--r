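#' Frontier orbital energies of a species
#'
#' @param e_homo Energy of the highest occupied molecular orbital, eV.
#' @param e_lumo Energy of the lowest unoccupied molecular orbital, eV;
#'   must be >= `e_homo`.
#' @param label Free-text species tag.
#' @return Object of class `orbital_energies`.
#' @export
orbital_energies <- function(e_homo, e_lumo, label = "") {
  if (!is.finite(e_homo) || !is.finite(e_lumo)) stop("orbital energies must be finite")
  if (e_homo > e_lumo) stop("e_homo must not exceed e_lumo")
  structure(list(e_homo = e_homo, e_lumo = e_lumo, label = as.character(label)),
            class = "orbital_energies")
}

#' Conceptual-DFT global reactivity descriptors
#'
#' From a HOMO/LUMO pair computes the frontier-orbital descriptors of
#' conceptual DFT:
#' \deqn{\Delta E = E_{LUMO} - E_{HOMO}, \quad
#'       \mu = (E_{LUMO} + E_{HOMO})/2, \quad
#'       \eta = \Delta E/2}
#' \deqn{I = -E_{HOMO}, \quad A = -E_{LUMO}, \quad
#'       \chi = (I + A)/2, \quad \omega = \mu^2/(2\eta)}
#' All quantities are in eV (electrophilicity on the eV scale).
#'
#' @param orbitals An [orbital_energies()] object (or anything with
#'   `e_homo`/`e_lumo` in eV).
#' @return Object of class `fmo_descriptors`: `energy_gap`,
#'   `chemical_potential`, `hardness`, `ionization_potential`,
#'   `electron_affinity`, `electronegativity`, `electrophilicity`, `label`.
#' @export
#' @examples
#' compute_descriptors(orbital_energies(-6.507, -0.933, "free digitoxin"))
compute_descriptors <- function(orbitals) {
  eh <- orbitals$e_homo; el <- orbitals$e_lumo
  if (eh == el) stop("zero hardness: electrophilicity undefined for e_homo == e_lumo")
  gap <- el - eh
  mu <- (el + eh) / 2
  eta <- gap / 2
  structure(list(
    energy_gap = gap,
    chemical_potential = mu,
    hardness = eta,
    ionization_potential = -eh,
    electron_affinity = -el,
    electronegativity = (-eh + -el) / 2,
    electrophilicity = mu^2 / (2 * eta),
    label = orbitals$label %||% ""), class = "fmo_descriptors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fmo_descriptors <- function(x, ...) {
  cat(sprintf("fmo_descriptors%s: gap %.4g eV, mu %.4g, eta %.4g, chi %.4g, omega %.9f\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$energy_gap, x$chemical_potential, x$hardness,
              x$electronegativity, x$electrophilicity))
  invisible(x)
}

#' Descriptor table for several species
#'
#' One column per species, rows in the conventional report order (HOMO,
#' LUMO, energy gap, chemical potential, hardness, ionization potential,
#' electron affinity, electronegativity, electrophilicity).
#'
#' @param orbital_sets List of [orbital_energies()] objects with unique
#'   labels.
#' @return Data frame with a `quantity` column plus one numeric column per
#'   species label.
#' @export
descriptor_table <- function(orbital_sets) {
  if (!length(orbital_sets)) stop("need at least one orbital set")
  labels <- vapply(orbital_sets, function(o) o$label, "")
  labels[!nzchar(labels)] <- paste0("species_", which(!nzchar(labels)))
  if (anyDuplicated(labels)) stop("duplicate labels in orbital sets")
  rows <- c("HOMO", "LUMO", "energy_gap", "chemical_potential", "hardness",
            "ionization_potential", "electron_affinity", "electronegativity",
            "electrophilicity")
  out <- data.frame(quantity = rows, stringsAsFactors = FALSE)
  for (i in seq_along(orbital_sets)) {
    o <- orbital_sets[[i]]
    d <- compute_descriptors(o)
    out[[labels[i]]] <- c(o$e_homo, o$e_lumo, d$energy_gap, d$chemical_potential,
                          d$hardness, d$ionization_potential, d$electron_affinity,
                          d$electronegativity, d$electrophilicity)
  }
  out
}

#' Read orbital energies from a delimited text file
#'
#' Expects columns `label`, `e_homo`, `e_lumo` (eV), comma or tab delimited,
#' `#` comments ignored.
#'
#' @param path File path.
#' @return List of [orbital_energies()] objects.
#' @export
read_orbitals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  delim <- detect_delim(lines)
  df <- utils::read.table(text = lines, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("label", "e_homo", "e_lumo")
  if (!all(need %in% names(df)))
    stop("orbital file must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    orbital_energies(df$e_homo[i], df$e_lumo[i], df$label[i]))
}
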