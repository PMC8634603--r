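#' Assemble connectome matrices from injection records
#'
#' Builds the target-by-source FLN and SLN matrices: per target area the
#' arithmetic mean FLN across replicate injections (absent connections
#' entering as 0, see [aggregate_fln()]) and the count-weighted mean SLN
#' (see [aggregate_sln()]). Intrinsic entries are fixed at exactly 0 in the
#' FLN matrix; SLN is `NA` wherever the connection is absent or the source
#' is agranular.
#'
#' @param injections List of [injection_record()]s.
#' @param sources Character vector of source-area codes defining the columns;
#'   defaults to the union of target areas and all observed source areas.
#' @param agranular Character vector of area codes without an identifiable
#'   layer 4 (SLN undefined there).
#' @return An object of class `connectome`: a list with elements `targets`,
#'   `sources`, `fln` (targets x sources), `sln`, `presence` (logical,
#'   `fln > 0`), `n_injections` (per target), `agranular`.
#' @export
build_connectome <- function(injections, sources = NULL, agranular = character()) {
  stopifnot(length(injections) >= 1L)
  targets <- sort(unique(vapply(injections, `[[`, character(1), "target_area")))
  observed <- sort(unique(unlist(lapply(injections, function(x) x$rows$source_area))))
  if (is.null(sources)) sources <- sort(unique(c(targets, observed)))
  unknown <- setdiff(observed, sources)
  if (length(unknown))
    stop("source area(s) not in parcellation list: ", paste(unknown, collapse = ", "))
  fln <- matrix(0, length(targets), length(sources),
                dimnames = list(targets, sources))
  sln <- matrix(NA_real_, length(targets), length(sources),
                dimnames = list(targets, sources))
  n_inj <- integer(length(targets)); names(n_inj) <- targets
  for (tg in targets) {
    grp <- Filter(function(x) x$target_area == tg, injections)
    n_inj[tg] <- length(grp)
    row <- aggregate_fln(grp)
    fln[tg, names(row)] <- row
    for (src in names(row)[row > 0]) {
      if (!(src %in% agranular)) sln[tg, src] <- aggregate_sln(grp, src)
    }
    fln[tg, tg] <- 0     # intrinsic connections are not quantified
    sln[tg, tg] <- NA_real_
  }
  structure(list(targets = targets, sources = sources, fln = fln, sln = sln,
                 presence = fln > 0, n_injections = n_inj,
                 agranular = agranular),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Interareal connectome: ", length(x$targets), " injected target areas x ",
      length(x$sources), " source areas\n", sep = "")
  cat("  ", sum(x$presence), " present connections of ",
      length(x$targets) * (length(x$sources) - 1L), " possible (",
      sprintf("%.1f%%", 100 * sum(x$presence) /
                (length(x$targets) * (length(x$sources) - 1L))), ")\n", sep = "")
  cat("  injections per target: ", paste(range(x$n_injections), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Edge-complete subnetwork
#'
#' Restricts the connectome to the injected target areas, giving the square
#' subnetwork in which every input and output has been measured. The diagonal
#' (intrinsic connections) is excluded from all downstream statistics.
#'
#' @param cm A `connectome` from [build_connectome()].
#' @return A list of class `edge_complete` with square matrices `fln`, `sln`,
#'   logical `adjacency`, and `areas`.
#' @export
build_edge_complete <- function(cm) {
  stopifnot(inherits(cm, "connectome"))
  missing <- setdiff(cm$targets, cm$sources)
  if (length(missing))
    stop("target area(s) absent from source list: ", paste(missing, collapse = ", "))
  idx <- cm$targets
  fln <- cm$fln[idx, idx, drop = FALSE]
  structure(list(areas = idx,
                 fln = fln,
                 sln = cm$sln[idx, idx, drop = FALSE],
                 adjacency = fln > 0),
            class = "edge_complete")
}

#' @export
print.edge_complete <- function(x, ...) {
  n <- length(x$areas)
  cat("Edge-complete subnetwork on ", n, " areas, density ",
      sprintf("%.2f%%", 100 * graph_density(x$adjacency)), "\n", sep = "")
  invisible(x)
}

#' Read / write delimited connectivity matrices
#'
#' Matrices are stored as delimited text with the first row holding source
#' codes and the first column target codes. Absent connections are written as
#' 0; undefined entries (e.g. SLN of an agranular source) as empty fields.
#'
#' @param file Path.
#' @param sep Field separator.
#' @return A numeric matrix with dimnames (targets, sources); empty fields
#'   become `NA`.
#' @export
read_matrix_csv <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_matrix_csv
#' @param m Matrix to write.
#' @export
write_matrix_csv <- function(m, file, sep = ",") {
  df <- data.frame(target = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(file)
}
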