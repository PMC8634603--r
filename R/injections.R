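#' Create a tracer injection record
#'
#' An injection record holds the labeled-cell counts recovered from a single
#' retrograde tracer injection: the injected (target) area, and for every
#' source area the number of labeled neurons found above (supragranular) and
#' below (infragranular) the centre of layer 4. A row whose source equals the
#' target is flagged intrinsic and excluded from all connection-weight
#' computations.
#'
#' @param injection_id Character scalar identifying the injection.
#' @param target_area Area code of the injected area.
#' @param rows Data frame with columns `source_area`, `supra_count`,
#'   `infra_count`; counts are non-negative integers, at most one row per
#'   source area, and every listed source has at least one labeled neuron.
#' @param tracer Tracer type, one of `"DY"`, `"FR"`, `"FB"`, `"FE"`,
#'   `"CTBgr"`, `"CTBr"`.
#' @param projection_lengths Optional numeric vector of per-neuron projection
#'   lengths in mm.
#' @param areas Optional character vector of valid parcellation codes; when
#'   supplied, every area code in the record is validated against it.
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(injection_id, target_area, rows,
                             tracer = c("DY", "FR", "FB", "FE", "CTBgr", "CTBr"),
                             projection_lengths = NULL, areas = NULL) {
  tracer <- match.arg(tracer)
  stopifnot(is.character(injection_id), length(injection_id) == 1L,
            is.character(target_area), length(target_area) == 1L,
            is.data.frame(rows))
  required <- c("source_area", "supra_count", "infra_count")
  if (!all(required %in% names(rows)))
    stop("rows must have columns source_area, supra_count, infra_count")
  rows <- rows[required]
  rows$source_area <- as.character(rows$source_area)
  if (anyDuplicated(rows$source_area))
    stop("at most one row per source area")
  counts <- c(rows$supra_count, rows$infra_count)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rows$supra_count + rows$infra_count < 1))
    stop("each listed source must have at least one labeled neuron")
  if (!is.null(areas)) {
    unknown <- setdiff(c(target_area, rows$source_area), areas)
    if (length(unknown))
      stop("unknown area code(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(projection_lengths)) {
    projection_lengths <- as.numeric(projection_lengths)
    if (any(projection_lengths < 0)) stop("projection lengths must be >= 0")
  }
  structure(list(injection_id = injection_id,
                 target_area = target_area,
                 tracer = tracer,
                 rows = rows,
                 projection_lengths = projection_lengths),
            class = "injection_record")
}

#' @export
print.injection_record <- function(x, ...) {
  extr <- x$rows$source_area != x$target_area
  cat("Retrograde tracer injection ", x$injection_id,
      " (", x$tracer, ") into ", x$target_area, "\n", sep = "")
  cat("  ", sum(extr), " extrinsic source areas, ",
      sum(x$rows$supra_count[extr] + x$rows$infra_count[extr]),
      " extrinsic labeled neurons\n", sep = "")
  if (!is.null(x$projection_lengths))
    cat("  ", length(x$projection_lengths), " per-neuron projection lengths\n",
        sep = "")
  invisible(x)
}

#' Fraction of extrinsic labeled neurons (FLN) for one injection
#'
#' Divides the labeled-neuron count of every extrinsic source area by the
#' total number of extrinsic labeled neurons, yielding the connection weight
#' from each source to the injected target. Intrinsic cells (source equal to
#' the target area) are excluded from both numerator and denominator.
#'
#' @param injection An [injection_record()].
#' @return Named numeric vector of FLN values in (0, 1], summing to 1.
#' @export
compute_fln <- function(injection) {
  stopifnot(inherits(injection, "injection_record"))
  rows <- injection$rows
  extr <- rows$source_area != injection$target_area
  rows <- rows[extr, , drop = FALSE]
  totals <- rows$supra_count + rows$infra_count
  denom <- sum(totals)
  if (denom == 0) stop("no extrinsic label: injection has zero extrinsic labeled neurons")
  fln <- totals / denom
  names(fln) <- rows$source_area
  fln
}

#' Fraction of supragranular labeled neurons (SLN)
#'
#' SLN = supragranular / (supragranular + infragranular) labeled neurons in a
#' source area. Values above 0.5 mark predominantly feedforward projections,
#' below 0.5 feedback. SLN is undefined for agranular sources, where no layer
#' 4 boundary exists to split the counts.
#'
#' @param supra_count,infra_count Non-negative labeled-neuron counts
#'   (vectorised).
#' @param agranular Logical (vectorised): `TRUE` marks a source without an
#'   identifiable layer 4, for which `NA` is returned.
#' @return Numeric vector of SLN values in `[0, 1]`, `NA` where undefined.
#' @export
compute_sln <- function(supra_count, infra_count, agranular = FALSE) {
  total <- supra_count + infra_count
  if (any(total < 1, na.rm = TRUE))
    stop("SLN requires at least one labeled neuron")
  sln <- supra_count / total
  sln[rep_len(agranular, length(sln))] <- NA_real_
  sln
}

#' Arithmetic mean FLN across replicate injections in one target
#'
#' A connection absent in some replicate contributes FLN = 0 for that
#' replicate, so the averaged row keeps summing to 1.
#'
#' @param injections List of [injection_record()]s sharing the same target
#'   area.
#' @return Named numeric vector over the union of source areas.
#' @export
aggregate_fln <- function(injections) {
  stopifnot(length(injections) >= 1L)
  targets <- vapply(injections, `[[`, character(1), "target_area")
  if (length(unique(targets)) != 1L)
    stop("injections must share the same target area")
  rows_list <- lapply(injections, compute_fln)
  sources <- sort(unique(unlist(lapply(rows_list, names))))
  acc <- matrix(0, nrow = length(injections), ncol = length(sources),
                dimnames = list(NULL, sources))
  for (i in seq_along(rows_list)) acc[i, names(rows_list[[i]])] <- rows_list[[i]]
  colMeans(acc)
}

#' Weighted mean SLN across replicate injections
#'
#' Per-injection SLN values are weighted by the injection's total
#' labeled-neuron count in that source, which makes the weighted mean equal
#' the pooled fraction: pooled supragranular count over pooled total count.
#'
#' @param injections List of [injection_record()]s sharing a target area.
#' @param source Source area code.
#' @return Weighted mean SLN, or `NA` if no injection reveals the connection.
#' @export
aggregate_sln <- function(injections, source) {
  supra <- 0; total <- 0
  for (inj in injections) {
    r <- inj$rows[inj$rows$source_area == source &
                    inj$rows$source_area != inj$target_area, , drop = FALSE]
    if (nrow(r)) {
      supra <- supra + r$supra_count
      total <- total + r$supra_count + r$infra_count
    }
  }
  if (total == 0) return(NA_real_)
  supra / total
}

#' Read / write injection tables
#'
#' The table format is delimited text with one row per (injection, source)
#' pair and columns `injection_id`, `target_area`, `source_area`,
#' `supra_count`, `infra_count`, plus an optional `tracer` column. An
#' optional companion lengths file has columns `injection_id`, `length_mm`.
#'
#' @param file Path of the injection table.
#' @param lengths_file Optional path of the per-neuron projection-length
#'   table.
#' @param sep Field separator (comma by default).
#' @param areas Optional vector of valid parcellation codes.
#' @return A list of [injection_record()]s.
#' @export
read_injections <- function(file, lengths_file = NULL, sep = ",", areas = NULL) {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  needed <- c("injection_id", "target_area", "source_area",
              "supra_count", "infra_count")
  if (!all(needed %in% names(tab)))
    stop("injection table must have columns ", paste(needed, collapse = ", "))
  tab$supra_count <- as.integer(tab$supra_count)
  tab$infra_count <- as.integer(tab$infra_count)
  lengths <- NULL
  if (!is.null(lengths_file)) {
    lengths <- utils::read.table(lengths_file, header = TRUE, sep = sep)
    if (!all(c("injection_id", "length_mm") %in% names(lengths)))
      stop("lengths table must have columns injection_id, length_mm")
  }
  ids <- unique(tab$injection_id)
  lapply(ids, function(id) {
    sub <- tab[tab$injection_id == id, , drop = FALSE]
    tracer <- if ("tracer" %in% names(sub)) sub$tracer[1] else "DY"
    pl <- if (!is.null(lengths)) {
      v <- lengths$length_mm[lengths$injection_id == id]
      if (length(v)) as.numeric(v) else NULL
    }
    injection_record(id, sub$target_area[1],
                     data.frame(source_area = sub$source_area,
                                supra_count = sub$supra_count,
                                infra_count = sub$infra_count,
                                stringsAsFactors = FALSE),
                     tracer = tracer, projection_lengths = pl, areas = areas)
  })
}

#' @rdname read_injections
#' @param injections List of [injection_record()]s to write.
#' @export
write_injections <- function(injections, file, lengths_file = NULL, sep = ",") {
  tabs <- lapply(injections, function(inj)
    data.frame(injection_id = inj$injection_id,
               target_area = inj$target_area,
               source_area = inj$rows$source_area,
               supra_count = inj$rows$supra_count,
               infra_count = inj$rows$infra_count,
               tracer = inj$tracer,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, tabs), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(lengths_file)) {
    lt <- lapply(injections, function(inj) {
      if (is.null(inj$projection_lengths)) return(NULL)
      data.frame(injection_id = inj$injection_id,
                 length_mm = inj$projection_lengths)
    })
    lt <- do.call(rbind, lt)
    if (!is.null(lt))
      utils::write.table(lt, lengths_file, sep = sep,
                         row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
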