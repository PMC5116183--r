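#' Annotate a collection of peptides against the reference array
#'
#' Runs the full per-record pipeline (cysteine profile, γ-core scan, slot
#' assignment, family classification, bond inference, notation) and
#' collects one row per record, in input order.  Records that cannot be
#' mapped (fewer than 2 or more than 12 cysteines) are retained with
#' family `"none"` and empty annotation fields.
#'
#' @param records List of [peptide_record]s.
#' @param long_extension_threshold See [classify_family()].
#' @param short_nloop_threshold See [toxin_flag()].
#' @param mytilin_exception See [map_to_reference()].
#' @return A data frame with columns `id`, `n_cysteines`, `slots`,
#'   `notation`, `family`, `bonds`, `gamma_core`, `kcxn`, `n_loop` and
#'   `toxin_heuristic`; the per-record mappings are attached as the
#'   `"mappings"` attribute (NULL for unmapped records).
#' @export
annotate_peptides <- function(records, long_extension_threshold = 10L,
                              short_nloop_threshold = 6L,
                              mytilin_exception = TRUE) {
  empty_row <- data.frame(
    id = character(0), n_cysteines = integer(0), slots = character(0),
    notation = character(0), family = character(0), bonds = character(0),
    gamma_core = character(0), kcxn = logical(0), n_loop = integer(0),
    toxin_heuristic = logical(0), stringsAsFactors = FALSE
  )
  if (!length(records)) {
    attr(empty_row, "mappings") <- list()
    return(empty_row)
  }
  rows <- vector("list", length(records))
  mappings <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    profile <- cysteine_profile(rec)
    row <- list(id = rec$id, n_cysteines = profile$count, slots = "",
                notation = "", family = "none", bonds = "",
                gamma_core = "", kcxn = FALSE, n_loop = NA_integer_,
                toxin_heuristic = FALSE)
    mapping <- tryCatch(
      map_to_reference(rec, profile, mytilin_exception = mytilin_exception),
      error = function(e) {
        warning("record ", rec$id, " not mapped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(mapping)) {
      fam <- classify_family(mapping, long_extension_threshold)
      bonds <- infer_bonds(mapping, fam)
      row$slots <- paste(sort(as.integer(names(mapping$assignment))),
                         collapse = ",")
      row$notation <- encode_notation(mapping)$string
      row$family <- fam$label
      row$bonds <- describe_bonds(bonds)
      if (!is.null(mapping$anchor_hit)) {
        row$gamma_core <- paste(mapping$anchor_hit$span, collapse = "-")
        row$kcxn <- mapping$anchor_hit$kcxn
      }
      row$n_loop <- n_loop_length(mapping)
      row$toxin_heuristic <- toxin_flag(
        mapping, short_nloop_threshold = short_nloop_threshold)
      mappings[[i]] <- mapping
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mappings") <- mappings
  out
}
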