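#' @include AllClasses.R
NULL

#' Published binding free energy reference table
#'
#' The replica-averaged MM-PB/SA component table reported for the five
#' ligands (ADE, 6AP, 3AY, 3TT, 2DY) bound to the C74U guanine riboswitch
#' aptamer, GR(C74U), and the adenine riboswitch aptamer, AR: long format
#' with one row per (ligand, aptamer, term). Terms are `dEele`, `dEvdw`,
#' `dEint`, `dGnonpol`, `dGpol`, the derived `dGelepol`, `dGvdwnonpol`,
#' `dH`, the entropy term `TdS`, `dGbind`, and the experimental `dGexp`
#' (available for seven complexes). Units kcal/mol; `se` is the standard
#' error over 10 replicas (`sd/sqrt(10)`).
#'
#' @return data.frame: `ligand`, `aptamer`, `term`, `mean`, `se`
#' @export
referenceBindingTable <- function() {
  utils::read.table(system.file("extdata", "riboswitch_binding_energies.tsv",
                                package = "ribostate"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Published conformational-state reference table
#'
#' Open/closed state percentages over the replica simulations of each
#' complex, together with the pocket distance between the mass center of
#' U51+A52 and the mass center of C74+C75 (A).
#'
#' @return data.frame: `ligand`, `aptamer`, `pct_open`, `pct_closed`,
#'   `distance`
#' @export
referenceStateTable <- function() {
  utils::read.table(system.file("extdata", "riboswitch_state_table.tsv",
                                package = "ribostate"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Audit the arithmetic identities of a binding table
#'
#' Recomputes every derived row (`dH`, `dGelepol`, `dGvdwnonpol`, `dGbind`)
#' of a long-format binding table from its component rows via
#' [bindingFreeEnergyResult()] and reports the deviation from the tabulated
#' values.
#'
#' @param tab data.frame as returned by [referenceBindingTable()].
#' @return data.frame: `ligand`, `aptamer`, `term`, `tabulated`,
#'   `recomputed`, `deviation`
#' @export
auditBindingTable <- function(tab) {
  out <- list()
  for (key in unique(paste(tab$ligand, tab$aptamer, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1L]]
    sub <- tab[tab$ligand == parts[1L] & tab$aptamer == parts[2L], ]
    g <- function(t) sub$mean[sub$term == t]
    res <- bindingFreeEnergyResult(g("dEele"), g("dEvdw"), g("dEint"),
                                   g("dGpol"), g("dGnonpol"), g("TdS"))
    for (t in c("dH", "dGelepol", "dGvdwnonpol", "dGbind"))
      out[[length(out) + 1L]] <- data.frame(
        ligand = parts[1L], aptamer = parts[2L], term = t,
        tabulated = g(t), recomputed = unname(res@means[t]),
        deviation = unname(res@means[t]) - g(t))
  }
  do.call(rbind, out)
}
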