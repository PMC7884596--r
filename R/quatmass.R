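# Mass and oxygen-binding-site accounting for hemocyanin oligomers.
# Molluscan hemocyanins assemble as decamers (10 subunits) that stack into
# didecamers and multidecamers; every FU carries one binuclear copper
# oxygen-binding site.

#' Describe a hemocyanin subunit type
#'
#' @param label Subunit name (e.g. `"NlH2"`, `"550kDa"`).
#' @param fu_count Number of functional units per subunit (8 for the typical
#'   400 kDa subunit, 12 for the mega-hemocyanin 550 kDa subunit).
#' @param subunit_mass_kda Subunit mass in kDa.
#' @param insert_mass_kda Mass of any extra (hydrophilic insertion) segment
#'   already contained in `subunit_mass_kda`; 0 if none.
#' @return A list of class `subunit_spec`.
#' @export
subunit_spec <- function(label, fu_count, subunit_mass_kda,
                         insert_mass_kda = 0) {
  stopifnot(fu_count >= 1, subunit_mass_kda >= 0, insert_mass_kda >= 0)
  structure(list(label = as.character(label), fu_count = as.integer(fu_count),
                 subunit_mass_kda = subunit_mass_kda,
                 insert_mass_kda = insert_mass_kda),
            class = "subunit_spec")
}

#' Describe an oligomer as stacked homodecamers
#'
#' Each decamer contributes exactly 10 subunits of one type; an oligomer is
#' a list of decamer types with counts (e.g. a didecamer is one type with
#' count 2; a mega-hemocyanin tridecamer is two typical decamers plus one
#' 12-FU decamer).
#'
#' @param subunits A `subunit_spec` or list of them, one per decamer type.
#' @param n_decamers Integer count of decamers per type (recycled).
#' @return Tibble of class `oligomer_spec` with one row per decamer type.
#' @examples
#' didecamer <- oligomer_spec(subunit_spec("NlH2", 8, 437, 41.4), 2)
#' count_binding_sites(didecamer)
#' @export
oligomer_spec <- function(subunits, n_decamers = 1) {
  if (inherits(subunits, "subunit_spec")) subunits <- list(subunits)
  stopifnot(all(vapply(subunits, inherits, TRUE, "subunit_spec")))
  n_decamers <- rep_len(as.integer(n_decamers), length(subunits))
  stopifnot(all(n_decamers >= 0))
  out <- dplyr::bind_rows(lapply(seq_along(subunits), function(i) {
    s <- subunits[[i]]
    tibble(label = s$label, fu_count = s$fu_count,
           subunit_mass_kda = s$subunit_mass_kda,
           insert_mass_kda = s$insert_mass_kda,
           n_decamers = n_decamers[i])
  }))
  out <- out[out$n_decamers > 0 | nrow(out) == 0, , drop = FALSE]
  class(out) <- c("oligomer_spec", class(out))
  out
}

#' Count oxygen-binding sites of an oligomer
#'
#' One site per FU, 10 subunits per decamer: the typical 8-FU tridecamer has
#' 240 sites, while a mega-hemocyanin tridecamer (two 8-FU decamers plus the
#' central 12-FU decamer) has 280 — 40 additional sites in the same outer
#' dimensions.
#'
#' @param o An [oligomer_spec()].
#' @return Integer site count.
#' @export
count_binding_sites <- function(o) {
  stopifnot(inherits(o, "oligomer_spec"))
  if (!nrow(o)) return(0L)
  as.integer(sum(10 * o$fu_count * o$n_decamers))
}

#' Total mass of an oligomer
#' @param o An [oligomer_spec()].
#' @return Mass in kDa.
#' @export
total_mass <- function(o) {
  stopifnot(inherits(o, "oligomer_spec"))
  sum(10 * o$subunit_mass_kda * o$n_decamers)
}

#' Extra (insertion) mass aggregated inside an oligomer
#'
#' The hydrophilic FU-g insertions of all subunits of the oligomer summed:
#' for a didecamer this is 20 times the per-subunit insert mass.
#'
#' @param o An [oligomer_spec()].
#' @return Mass in kDa.
#' @export
extra_mass <- function(o) {
  stopifnot(inherits(o, "oligomer_spec"))
  sum(10 * o$insert_mass_kda * o$n_decamers)
}

#' Full mass/site report for an oligomer
#'
#' @param o An [oligomer_spec()].
#' @return A list of class `mass_report`: `total_mass_kda`, `binding_sites`,
#'   `extra_mass_kda`, and per-decamer-type `breakdown` tibble.
#' @export
mass_report <- function(o) {
  stopifnot(inherits(o, "oligomer_spec"))
  breakdown <- mutate(as_tibble(o),
                      decamer_mass_kda = 10 * .data$subunit_mass_kda,
                      decamer_sites = 10L * .data$fu_count,
                      decamer_extra_kda = 10 * .data$insert_mass_kda)
  structure(list(total_mass_kda = total_mass(o),
                 binding_sites = count_binding_sites(o),
                 extra_mass_kda = extra_mass(o),
                 breakdown = breakdown),
            class = "mass_report")
}

#' @export
print.mass_report <- function(x, ...) {
  cat("<mass_report> total ", format(round(x$total_mass_kda, 1)), " kDa, ",
      x$binding_sites, " O2-binding sites, extra mass ",
      format(round(x$extra_mass_kda, 1)), " kDa\n", sep = "")
  invisible(x)
}

#' Build an oligomer spec from a characterized protein
#'
#' Bridges the protein characterization to the mass accounting: subunit mass
#' from [molecular_weight()], FU count from an [annotate_fus()] result,
#' insert mass from [call_insertion()] calls.
#'
#' @param p A `protein_record` (or sequence).
#' @param fu_annotation An [annotate_fus()] tibble for `p`.
#' @param insertions A [call_insertion()] tibble (may have zero rows).
#' @param n_decamers How many decamers the oligomer stacks (2 = didecamer);
#'   0 gives an empty spec.
#' @param label Subunit label.
#' @return An [oligomer_spec()].
#' @export
build_from_protein <- function(p, fu_annotation, insertions = NULL,
                               n_decamers = 2, label = NULL) {
  if (!inherits(fu_annotation, "fu_annotation") || !nrow(fu_annotation))
    stop("a non-empty FU annotation is required")
  rec <- if (inherits(p, "protein_record")) p else protein_record(p)
  ins_kda <- if (is.null(insertions) || !nrow(insertions)) 0 else
    sum(insertions$mass_da) / 1000
  s <- subunit_spec(label = if (is.null(label)) rec$id else label,
                    fu_count = nrow(fu_annotation),
                    subunit_mass_kda = rec$mass_da / 1000,
                    insert_mass_kda = ins_kda)
  oligomer_spec(s, n_decamers)
}
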