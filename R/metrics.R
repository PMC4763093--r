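# The derived morphometric suite for one colony: theoretic surface area and
# volume (unsampled minus sampled underwater models), biosurface and biomass
# (fresh-tissue minus bleached-skeleton dry models), sample-to-colony scale
# percentages, and the associated error statistics. Absent raw measurements
# (e.g. volumes of colonies whose models never closed) propagate as NA,
# never as zero.

measurement_fields <- c(
  "unsampled_sa", "tsa_sampled", "esa_sampled",
  "tsa_tissue", "esa_tissue", "tsa_skeleton", "esa_skeleton",
  "unsampled_v", "tv_sampled", "tv_tissue", "tv_skeleton", "tv_water")

growth_forms <- c("massive", "branched", "tabular", "crustose", "foliose")

#' Raw measurements of one colony
#'
#' The non-derived quantities measured on the digital models of a single
#' colony: surface areas (cm^2) of the underwater unsampled and sampled
#' models (total and effective) and of the dry fresh-tissue and bleached-
#' skeleton sample models, the corresponding volumes (cm^3), and the
#' water-displacement volume of the bleached skeleton. Any quantity may be
#' absent (`NA`) — underwater volumes are genuinely not computable for
#' growth forms whose models never close.
#'
#' @param name colony identifier.
#' @param growth_form one of `"massive"`, `"branched"`, `"tabular"`,
#'   `"crustose"`, `"foliose"`, or `NA`.
#' @param unsampled_sa,tsa_sampled,esa_sampled underwater surface areas,
#'   cm^2.
#' @param tsa_tissue,esa_tissue,tsa_skeleton,esa_skeleton dry surface areas,
#'   cm^2.
#' @param unsampled_v,tv_sampled underwater volumes, cm^3.
#' @param tv_tissue,tv_skeleton dry volumes, cm^3.
#' @param tv_water water-displacement volume of the skeleton, cm^3.
#' @return An object of class `colony_measurements`.
#' @export
colony_measurements <- function(name = NA_character_,
                                growth_form = NA_character_,
                                unsampled_sa = NA_real_,
                                tsa_sampled = NA_real_,
                                esa_sampled = NA_real_,
                                tsa_tissue = NA_real_,
                                esa_tissue = NA_real_,
                                tsa_skeleton = NA_real_,
                                esa_skeleton = NA_real_,
                                unsampled_v = NA_real_,
                                tv_sampled = NA_real_,
                                tv_tissue = NA_real_,
                                tv_skeleton = NA_real_,
                                tv_water = NA_real_) {
  if (!is.na(growth_form))
    growth_form <- match.arg(growth_form, growth_forms)
  vals <- stats::setNames(
    vapply(measurement_fields, function(f) as.numeric(get(f)), 0),
    measurement_fields)
  neg <- !is.na(vals) & vals < 0
  if (any(neg))
    stop("raw measurements must be non-negative: ",
         paste(names(vals)[neg], collapse = ", "), call. = FALSE)
  structure(c(list(name = as.character(name), growth_form = growth_form),
              as.list(vals)),
            class = "colony_measurements")
}

#' @export
print.colony_measurements <- function(x, ...) {
  cat(sprintf("<colony_measurements> %s (%s)\n", x$name, x$growth_form))
  for (f in measurement_fields)
    cat(sprintf("  %-13s %s\n", f,
                if (is.na(x[[f]])) "-" else format(x[[f]])))
  invisible(x)
}

# Binary helpers: NA-propagating difference / percentage.
na_diff <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else a - b
na_pct <- function(num, den) {
  if (is.na(num) || is.na(den) || den <= 0) NA_real_ else 100 * num / den
}
na_rel_err <- function(x, ref) {
  if (is.na(x) || is.na(ref) || ref <= 0) NA_real_ else 100 * abs(x - ref) / ref
}

#' Theoretic surface area / volume
#'
#' The underwater difference between the unsampled and the sampled colony
#' model: `theoretic_sa = unsampled_sa - esa_sampled` and
#' `theoretic_v = unsampled_v - tv_sampled`. This is the pipeline's indirect
#' estimate of the removed sample's surface area / volume. The difference is
#' kept signed — a negative value records that the sampled model came out
#' larger, itself a useful diagnostic of reconstruction error.
#'
#' @param m a [colony_measurements()].
#' @return Signed difference in cm^2 / cm^3, or `NA` if an operand is
#'   absent.
#' @export
theoretic_sa <- function(m) na_diff(m$unsampled_sa, m$esa_sampled)

#' @rdname theoretic_sa
#' @export
theoretic_v <- function(m) na_diff(m$unsampled_v, m$tv_sampled)

#' Biosurface and biomass
#'
#' Dry-imaging differences between the fresh-tissue and bleached-skeleton
#' sample models: `biosurface = tsa_tissue - tsa_skeleton` (cm^2) and
#' `biomass = tv_tissue - tv_skeleton` (cm^3) — proxies for the living
#' tissue surface and volume. Signed: mucus filling corallite cavities
#' during fresh imaging can make the skeleton model the larger one.
#'
#' @param m a [colony_measurements()].
#' @return Signed difference, or `NA` if an operand is absent.
#' @export
biosurface <- function(m) na_diff(m$tsa_tissue, m$tsa_skeleton)

#' @rdname biosurface
#' @export
biomass <- function(m) na_diff(m$tv_tissue, m$tv_skeleton)

#' Sample-to-colony scale percentages
#'
#' The size of the dry-imaged sample relative to the whole underwater
#' colony: `100 * esa_tissue / unsampled_sa` and
#' `100 * tv_tissue / unsampled_v`.
#'
#' @param m a [colony_measurements()].
#' @return Percentage, or `NA` when the denominator is absent or zero.
#' @export
pct_scale_sa <- function(m) na_pct(m$esa_tissue, m$unsampled_sa)

#' @rdname pct_scale_sa
#' @export
pct_scale_v <- function(m) na_pct(m$tv_tissue, m$unsampled_v)

#' Theoretical error of the underwater difference estimates
#'
#' Relative discrepancy between the theoretic (underwater-difference)
#' estimate of the removed sample and its direct dry measurement:
#' `100 * |theoretic_sa - esa_tissue| / esa_tissue` and
#' `100 * |theoretic_v - tv_tissue| / tv_tissue`. The dry tissue measurement
#' is the denominator; the theoretic estimate enters signed inside the
#' absolute value.
#'
#' @param m a [colony_measurements()].
#' @return Non-negative percentage, or `NA` if an operand is absent.
#' @export
theoretical_error_sa <- function(m) na_rel_err(theoretic_sa(m), m$esa_tissue)

#' @rdname theoretical_error_sa
#' @export
theoretical_error_v <- function(m) na_rel_err(theoretic_v(m), m$tv_tissue)

#' Skeleton-volume error against water displacement
#'
#' Relative discrepancy between the digital bleached-skeleton volume and the
#' physically measured water-displacement volume:
#' `100 * |tv_skeleton - tv_water| / tv_water`.
#'
#' @param m a [colony_measurements()].
#' @return Non-negative percentage, or `NA` if an operand is absent.
#' @export
error_tvw <- function(m) na_rel_err(m$tv_skeleton, m$tv_water)

report_fields <- c("thsa", "thv", "biosurface", "biomass",
                   "pct_scale_sa", "pct_scale_v",
                   "theoretical_error_sa", "theoretical_error_v",
                   "error_tvw")

#' Full derived-metric report for one colony
#'
#' Computes all nine derived quantities at full precision (rounding happens
#' only at serialization): theoretic SA/V, biosurface, biomass, % scale
#' (SA and V), theoretical error (SA and V) and the skeleton-vs-water volume
#' error. Absent operands propagate as `NA`.
#'
#' @param m a [colony_measurements()].
#' @return A one-row data frame with columns `name`, `growth_form` and the
#'   nine derived metrics.
#' @export
full_report <- function(m) {
  stopifnot(inherits(m, "colony_measurements"))
  data.frame(
    name = m$name,
    growth_form = m$growth_form,
    thsa = theoretic_sa(m),
    thv = theoretic_v(m),
    biosurface = biosurface(m),
    biomass = biomass(m),
    pct_scale_sa = pct_scale_sa(m),
    pct_scale_v = pct_scale_v(m),
    theoretical_error_sa = theoretical_error_sa(m),
    theoretical_error_v = theoretical_error_v(m),
    error_tvw = error_tvw(m),
    stringsAsFactors = FALSE)
}

#' Read a colony measurements table from CSV
#'
#' One header row with columns named as the [colony_measurements()] fields
#' (`name`, `growth_form`, then the twelve raw quantities); empty cells are
#' absent values. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return A list of [colony_measurements()] records.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(measurement_fields, names(df))
  if (length(missing_cols))
    stop("measurements CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(c("name", "growth_form",
                                      measurement_fields), names(df))])
    args <- lapply(args, function(x) if (is.character(x) && !nzchar(x)) NA
                   else x)
    do.call(colony_measurements, args)
  })
}

#' Derived-metric table for a set of colonies
#'
#' Applies [full_report()] to each record and binds the rows, preserving
#' input order.
#'
#' @param measurements a list of [colony_measurements()] records (e.g. from
#'   [read_measurements()]).
#' @return A data frame, one row per colony.
#' @export
report_table <- function(measurements) {
  if (inherits(measurements, "colony_measurements"))
    measurements <- list(measurements)
  if (length(measurements) == 0L)
    return(full_report(colony_measurements())[0L, , drop = FALSE])
  do.call(rbind, lapply(measurements, full_report))
}

#' Write a derived-metric table as machine-readable CSV
#'
#' Values are printed with two decimals, `.` decimal separator and no
#' thousands separators; absent values are empty cells. A comment header
#' records the package version and options for provenance.
#'
#' @param report data frame from [report_table()].
#' @param path output CSV path.
#' @param digits decimal places (default 2).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = 2L) {
  out <- report
  num <- vapply(out, is.numeric, TRUE)
  for (j in which(num))
    out[[j]] <- ifelse(is.na(out[[j]]), "",
                       formatC(out[[j]], format = "f", digits = digits))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# coralmesh %s derived-metric report (digits = %d)",
                     as.character(utils::packageVersion("coralmesh")),
                     digits), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
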