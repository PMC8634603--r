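#' Read a microstructure table
#'
#' Delimited text with columns `group`, `member_areas` (semicolon-separated
#' parcellation codes sharing one measurement), `spine_count` (spines per
#' basal dendritic tree of a layer-3 pyramidal neuron), and optional
#' `neural_density` and `rostrocaudal_mm`.
#'
#' @param file Path.
#' @param sep Field separator.
#' @return Data frame with `member_areas` parsed to a list column.
#' @export
read_microstructure <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("group", "member_areas", "spine_count") %in% names(tab)))
  if (any(tab$spine_count <= 0)) stop("spine counts must be positive")
  tab$member_areas <- strsplit(tab$member_areas, ";", fixed = TRUE)
  if (any(!lengths(tab$member_areas))) stop("member_areas must be nonempty")
  tab
}

#' Correlate spine counts with hierarchical position
#'
#' Hierarchy indices are normalized to a maximum of 1 and averaged within
#' each area group sharing one spine-count measurement; the Pearson
#' correlation of group spine counts with group-mean hierarchy is returned.
#' Groups with no member matched to the hierarchy are excluded with a
#' warning. With `mode = "duplicate"`, each member area instead keeps its
#' own hierarchy value and the group's spine count is duplicated across
#' members.
#'
#' @param table Microstructure table (see [read_microstructure()]).
#' @param hierarchy Named hierarchy indices (e.g. `coef()` of a
#'   [fit_hierarchy()] result).
#' @param mode `"group"` (average hierarchy within groups, default) or
#'   `"duplicate"`.
#' @return List with `r`, `p`, `n`, and the matched data frame.
#' @export
correlate_spine_hierarchy <- function(table, hierarchy,
                                      mode = c("group", "duplicate")) {
  mode <- match.arg(mode)
  h <- hierarchy / max(hierarchy)
  if (mode == "group") {
    hm <- vapply(table$member_areas, function(a) {
      m <- h[intersect(a, names(h))]
      if (length(m)) mean(m) else NA_real_
    }, numeric(1))
    df <- data.frame(group = table$group, spine_count = table$spine_count,
                     hierarchy = hm)
  } else {
    df <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
      a <- intersect(table$member_areas[[i]], names(h))
      if (!length(a)) return(data.frame(group = table$group[i],
                                        spine_count = table$spine_count[i],
                                        hierarchy = NA_real_))
      data.frame(group = table$group[i], spine_count = table$spine_count[i],
                 hierarchy = unname(h[a]))
    }))
  }
  drop <- is.na(df$hierarchy)
  if (any(drop))
    warning(sum(drop), " group(s) had no member matched to the hierarchy")
  df <- df[!drop, , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 matched groups")
  ct <- stats::cor.test(df$spine_count, df$hierarchy)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df), data = df)
}

#' Power-law fit of spine count versus neural density
#'
#' Ordinary least squares of `log10(spine_count)` on
#' `log10(neural_density)`; an exponent near -3 means spine counts grow as
#' the inverse cube of neural density.
#'
#' @param spine_count,neural_density Positive paired vectors (>= 3 values).
#' @return List with `exponent`, `intercept`, `r_squared`, `n`.
#' @export
fit_density_powerlaw <- function(spine_count, neural_density) {
  stopifnot(length(spine_count) == length(neural_density))
  keep <- !is.na(spine_count) & !is.na(neural_density)
  spine_count <- spine_count[keep]; neural_density <- neural_density[keep]
  if (length(spine_count) < 3) stop("need at least 3 paired values")
  if (any(spine_count <= 0) || any(neural_density <= 0))
    stop("values must be positive")
  fit <- stats::lm(log10(spine_count) ~ log10(neural_density))
  list(exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(spine_count))
}

#' Correlate spine counts with rostrocaudal position
#'
#' Pearson correlation of group spine counts with the rostrocaudal
#' coordinate.
#'
#' @param table Microstructure table with a `rostrocaudal_mm` column.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_rostrocaudal <- function(table) {
  if (!("rostrocaudal_mm" %in% names(table)) ||
      all(is.na(table$rostrocaudal_mm)))
    stop("rostrocaudal coordinates missing")
  keep <- !is.na(table$rostrocaudal_mm) & !is.na(table$spine_count)
  ct <- stats::cor.test(table$spine_count[keep], table$rostrocaudal_mm[keep])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
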