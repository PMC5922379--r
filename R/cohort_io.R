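#' Construct an expression matrix
#'
#' Thin validated container for probes-by-patients continuous signals
#' (microarray-scale arbitrary units). Stored as a plain numeric matrix
#' with probe and patient ids as dimnames.
#'
#' @param probe_ids,patient_ids unique character vectors.
#' @param values numeric matrix, `length(probe_ids)` x
#'   `length(patient_ids)`, all finite.
#' @return An `expression_matrix` (numeric matrix subclass).
#' @export
expression_matrix <- function(probe_ids, patient_ids, values) {
  probe_ids <- as.character(probe_ids)
  patient_ids <- as.character(patient_ids)
  values <- as.matrix(values)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1L], call. = FALSE)
  if (anyDuplicated(patient_ids))
    stop("duplicate patient id: ", patient_ids[duplicated(patient_ids)][1L], call. = FALSE)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(patient_ids))
    stop("expression dimensions do not match id vectors", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  dimnames(values) <- list(probe_ids, patient_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read / write an expression matrix as TSV
#'
#' Format: header line `probe_id<TAB>patient ids...`, one row per
#' probe, plain decimal values. `write_expression` prints values with
#' 17 significant digits so a write/read round trip reproduces the
#' doubles exactly.
#'
#' @param path file path.
#' @return `read_expression`: an [expression_matrix()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) stop("expression header has no patient columns", call. = FALSE)
  patient_ids <- header[-1L]
  probe_ids <- character(length(lines) - 1L)
  values <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = n_col - 1L)
  for (i in seq_along(probe_ids)) {
    row <- fields[[i + 1L]]
    if (length(row) != n_col)
      stop(sprintf("ragged row at line %d of %s (expected %d fields, got %d)",
                   i + 1L, path, n_col, length(row)), call. = FALSE)
    probe_ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v))
      stop(sprintf("non-numeric expression value at line %d of %s", i + 1L, path),
           call. = FALSE)
    values[i, ] <- v
  }
  expression_matrix(probe_ids, patient_ids, values)
}

#' @param expr an [expression_matrix()].
#' @rdname read_expression
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  header <- paste(c("probe_id", colnames(expr)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i)
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a clinical table as CSV
#'
#' Requires columns `patient_id`, `os_months` (non-negative),
#' `os_event` (0/1); additional covariate columns pass through
#' unchanged, missing values allowed.
#'
#' @param path file path.
#' @return `read_clinical`: a validated `data.frame`.
#' @export
read_clinical <- function(path) {
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(clin)
}

#' @param clin clinical `data.frame`.
#' @rdname read_clinical
#' @export
write_clinical <- function(clin, path) {
  validate_clinical(clin)
  utils::write.csv(clin, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_clinical <- function(clin) {
  required <- c("patient_id", "os_months", "os_event")
  missing <- setdiff(required, names(clin))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(clin$patient_id))
    stop("duplicate patient id in clinical table", call. = FALSE)
  if (any(!is.finite(clin$os_months)) || any(clin$os_months < 0))
    stop("'os_months' must be finite and non-negative", call. = FALSE)
  if (!all(clin$os_event %in% c(0, 1)))
    stop("'os_event' must be 0 or 1", call. = FALSE)
  clin$patient_id <- as.character(clin$patient_id)
  clin
}

#' Align an expression matrix and clinical table on shared patients
#'
#' Restricts both components to the intersection of patient ids, in the
#' expression matrix's column order, and reports dropped patients.
#'
#' @param expr an [expression_matrix()].
#' @param clin clinical `data.frame`.
#' @return list `(expr, clin)` with identical patient order.
#' @export
align_cohort <- function(expr, clin) {
  clin <- validate_clinical(clin)
  shared <- intersect(colnames(expr), clin$patient_id)
  if (length(shared) < 2L)
    stop("fewer than 2 shared patients between expression and clinical data",
         call. = FALSE)
  dropped <- (ncol(expr) - length(shared)) + (nrow(clin) - length(shared))
  if (dropped > 0L)
    message(dropped, " patient record(s) without a match dropped during alignment")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  expr2 <- expr[, shared, drop = FALSE]
  class(expr2) <- class(expr)
  clin2 <- clin[match(shared, clin$patient_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr2, clin = clin2)
}

#' Construct a frozen risk-score model
#'
#' The trained object applied unchanged to validation cohorts: one row
#' per retained gene (probe id, expression cutoff, Cox log hazard ratio
#' `beta`, risk `direction`: +1 if above-cutoff is the high-risk side),
#' plus the frozen map from high-gene counts 0..K to merged risk-group
#' labels and training metadata. Ties at a cutoff score as the low
#' side.
#'
#' @param genes `data.frame` with columns `probe_id`, `cutoff`, `beta`,
#'   `direction` (+1/-1).
#' @param merge_map integer vector of merged group labels, one per high
#'   count 0..K (names "0".."K"); labels must start at 1, be
#'   non-decreasing and contiguous.
#' @param metadata list of training settings (alpha levels, minprop,
#'   seed, ...).
#' @return An `episcore_model`.
#' @export
episcore_model <- function(genes, merge_map, metadata = list()) {
  need <- c("probe_id", "cutoff", "beta", "direction")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("model schema error: 'genes' needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(genes) < 1L) stop("model schema error: no genes", call. = FALSE)
  if (any(!is.finite(genes$cutoff)))
    stop("model schema error: non-finite cutoff", call. = FALSE)
  if (any(!is.finite(genes$beta)))
    stop("model schema error: non-finite beta", call. = FALSE)
  if (!all(genes$direction %in% c(-1, 1)))
    stop("model schema error: direction must be +1 or -1", call. = FALSE)
  k <- nrow(genes)
  merge_map <- unlist(merge_map)
  counts <- as.character(0:k)
  if (is.null(names(merge_map)) || !setequal(names(merge_map), counts))
    stop("model schema error: merge map must cover every count 0..", k,
         call. = FALSE)
  merge_map <- as.integer(merge_map[counts])
  if (anyNA(merge_map) || merge_map[1L] != 1L || any(diff(merge_map) < 0) ||
      any(diff(merge_map) > 1L))
    stop("model schema error: merge labels must be ordered and contiguous from 1",
         call. = FALSE)
  names(merge_map) <- counts
  genes$probe_id <- as.character(genes$probe_id)
  genes$cutoff <- as.numeric(genes$cutoff)
  genes$beta <- as.numeric(genes$beta)
  genes$direction <- as.numeric(genes$direction)
  rownames(genes) <- NULL
  structure(list(genes = genes[need], merge_map = merge_map,
                 metadata = metadata),
            class = "episcore_model")
}

#' Read / write a frozen risk-score model as JSON
#'
#' Full-precision round trip: numeric fields are serialized with all
#' significant digits.
#'
#' @param path file path.
#' @return `read_model`: an [episcore_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("genes", "merge_map"))
    if (is.null(obj[[field]]))
      stop("model schema error: missing field '", field, "'", call. = FALSE)
  episcore_model(as.data.frame(obj$genes, stringsAsFactors = FALSE),
                 obj$merge_map,
                 if (is.null(obj$metadata)) list() else obj$metadata)
}

#' @param model an [episcore_model()].
#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "episcore_model"))
  jsonlite::write_json(
    list(genes = model$genes, merge_map = as.list(model$merge_map),
         metadata = model$metadata),
    path, auto_unbox = TRUE, digits = 17, pretty = TRUE)
  invisible(path)
}
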