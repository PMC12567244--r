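#' Selectivity index from an IC50 pair
#'
#' Ratio of the half-maximal inhibitory concentration in a normal cell line
#' to that in a tumor line, `SI = IC50(normal) / IC50(tumor)`. Values above
#' 1 mean the compound is more toxic to the tumor line than to normal cells;
#' the larger the SI, the more tumor-selective (safer) the compound. The
#' ratio is unit-free: any common concentration unit cancels. Returned at
#' full precision — round only for display (conventionally 2 decimals).
#'
#' @param ic50_normal,ic50_tumor Positive finite IC50 values in a common
#'   concentration unit (vectorized).
#' @return Numeric vector of selectivity indices.
#' @examples
#' round(selectivity_index(81.65, 3.98), 2)  # 20.51
#' @export
selectivity_index <- function(ic50_normal, ic50_tumor) {
  stopifnot(is.numeric(ic50_normal), is.numeric(ic50_tumor))
  if (any(!is.finite(ic50_normal)) || any(!is.finite(ic50_tumor)) ||
      any(ic50_normal <= 0) || any(ic50_tumor <= 0))
    stop("IC50 values must be positive and finite", call. = FALSE)
  ic50_normal / ic50_tumor
}

#' Display a selectivity index at reporting precision
#'
#' Truncates (rounds toward zero) to `digits` decimals. Reported SI tables
#' in the cytotoxicity literature are commonly truncated rather than
#' rounded (81.65/3.98 = 20.5151 is reported as 20.51, 81.65/5.90 = 13.8389
#' as 13.83); this helper reproduces that display convention. Computation
#' always uses the full-precision ratio from [selectivity_index()].
#'
#' @param si Numeric selectivity indices.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector truncated to `digits` decimals.
#' @export
display_si <- function(si, digits = 2L) {
  scale <- 10^digits
  trunc(si * scale + sign(si) * 1e-9) / scale
}

#' Selectivity-index table from a long-format IC50 table
#'
#' Computes the SI of every compound against every tumor line, using the
#' compound's IC50 in the designated normal line as numerator. Uncertainty
#' columns (`sd`), if present, are carried through unchanged but not
#' propagated into the SI.
#'
#' @param ic50 Long-format `data.frame` with columns `compound_id`,
#'   `cell_line`, `ic50` (optional `sd`). Each compound must have exactly
#'   one row for the normal line.
#' @param normal_line Name of the normal cell line (default `"WI-38"`,
#'   human lung fibroblasts).
#' @return `data.frame` with one row per compound x tumor line:
#'   `compound_id`, `cell_line`, `ic50_tumor`, `ic50_normal`, `si`,
#'   sorted as in the input.
#' @export
si_table <- function(ic50, normal_line = "WI-38") {
  req <- c("compound_id", "cell_line", "ic50")
  missing_cols <- setdiff(req, names(ic50))
  if (length(missing_cols))
    stop("IC50 table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(ic50) == 0L)
    return(data.frame(compound_id = character(0), cell_line = character(0),
                      ic50_tumor = numeric(0), ic50_normal = numeric(0),
                      si = numeric(0)))
  ids <- as.character(ic50$compound_id)
  lines <- as.character(ic50$cell_line)
  bad <- which(!is.finite(ic50$ic50) | ic50$ic50 <= 0)
  if (length(bad))
    stop("non-positive IC50 for compound ", ids[bad[1L]],
         " on line ", lines[bad[1L]], call. = FALSE)
  if (!normal_line %in% lines)
    stop("normal line '", normal_line, "' not found in IC50 table",
         call. = FALSE)

  is_normal <- lines == normal_line
  normal <- ic50[is_normal, , drop = FALSE]
  dup <- unique(normal$compound_id[duplicated(normal$compound_id)])
  if (length(dup))
    stop("multiple ", normal_line, " rows for compound: ",
         paste(dup, collapse = ", "), call. = FALSE)
  tumor <- ic50[!is_normal, , drop = FALSE]
  miss <- setdiff(unique(as.character(tumor$compound_id)),
                  as.character(normal$compound_id))
  if (length(miss))
    stop("no ", normal_line, " IC50 for compound(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  m <- match(as.character(tumor$compound_id), as.character(normal$compound_id))
  out <- data.frame(
    compound_id = as.character(tumor$compound_id),
    cell_line = as.character(tumor$cell_line),
    ic50_tumor = tumor$ic50,
    ic50_normal = normal$ic50[m],
    stringsAsFactors = FALSE
  )
  out$si <- selectivity_index(out$ic50_normal, out$ic50_tumor)
  if ("sd" %in% names(tumor)) out$sd_tumor <- tumor$sd
  rownames(out) <- NULL
  out
}
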