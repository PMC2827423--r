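#' Analysis control parameters
#'
#' Bundles the tunable parameters of the reference-gene stability pipeline,
#' analogous to [glm.control()]. All defaults follow common qPCR practice for
#' SYBR-green assays analysed at a fixed fluorescence threshold.
#'
#' @param threshold_fraction Fraction of the baseline-corrected plateau
#'   fluorescence at which the cycle threshold (CT) is called. Default 0.20
#'   (a manually set threshold of 20% of total fluorescence).
#' @param efficiency_mode How per-cell amplification efficiencies are resolved:
#'   `"fixed"` uses `fixed_efficiency` everywhere, `"per_gene"` averages
#'   observed per-reaction efficiencies within each gene, `"per_reaction"`
#'   averages them within each technical-replicate group.
#' @param fixed_efficiency Amplification factor per cycle used when
#'   `efficiency_mode = "fixed"`; must lie in (1, 2]. Default 2 (perfect
#'   doubling).
#' @param replicate_max_range Maximum allowed CT spread (cycles) within a
#'   technical-replicate group; groups whose range is `>=` this value are
#'   discarded. Default 1 cycle ("differing by less than one cycle").
#' @param alpha Significance level for the group-difference testing cascade.
#'   Default 0.05.
#' @param pv_cutoff Pairwise-variation cutoff below which adding a further
#'   reference gene is deemed unnecessary. Default 0.15.
#' @param global_reference If `TRUE` relative quantities are rescaled to the
#'   single sample holding the lowest CT anywhere in the matrix; if `FALSE`
#'   (default) each gene is rescaled to its own lowest-CT sample.
#' @param baseline_window Inclusive cycle range over which the linear
#'   background is fitted and subtracted before CT calling, or `NULL` for
#'   curves that are already baseline-corrected. Default cycles 3 to 10.
#' @param ce_params Cross-Entropy optimizer parameters, see [ce_params()].
#'
#' @return A list of class `"refstab_control"`.
#' @seealso [refstab()], [ce_params()]
#' @export
#' @examples
#' refstab_control(efficiency_mode = "per_reaction")
refstab_control <- function(threshold_fraction = 0.20,
                            efficiency_mode = c("fixed", "per_gene", "per_reaction"),
                            fixed_efficiency = 2,
                            replicate_max_range = 1,
                            alpha = 0.05,
                            pv_cutoff = 0.15,
                            global_reference = FALSE,
                            baseline_window = c(3L, 10L),
                            ce_params = NULL) {
  efficiency_mode <- match.arg(efficiency_mode)
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            fixed_efficiency > 1, fixed_efficiency <= 2,
            replicate_max_range > 0,
            alpha > 0, alpha < 1,
            pv_cutoff > 0)
  if (!is.null(baseline_window)) {
    stopifnot(length(baseline_window) == 2, baseline_window[1] >= 1,
              baseline_window[2] >= baseline_window[1])
  }
  structure(list(threshold_fraction = threshold_fraction,
                 efficiency_mode = efficiency_mode,
                 fixed_efficiency = fixed_efficiency,
                 replicate_max_range = replicate_max_range,
                 alpha = alpha,
                 pv_cutoff = pv_cutoff,
                 global_reference = global_reference,
                 baseline_window = baseline_window,
                 ce_params = ce_params),
            class = "refstab_control")
}

.reaction_cols <- c("line", "organ", "stage", "bio_rep", "tech_rep", "gene", "ct")

#' Read a qPCR reaction table
#'
#' Reads a delimited text file with one row per PCR reaction. The file must be
#' comma-separated, UTF-8, with `.` as decimal separator and the literal token
#' `NA` for missing values. Required columns: `line`, `organ`, `stage`,
#' `bio_rep`, `tech_rep`, `gene`, `ct`; an `efficiency` column is optional.
#' A missing efficiency column is filled according to `control$efficiency_mode`
#' (with `fixed_efficiency` under the default fixed mode, e.g. 2 for a
#' perfectly doubling assay).
#'
#' Rows that cannot be parsed are rejected, never silently coerced: each
#' rejected row is reported with its row number. Rows whose CT is missing are
#' kept but flagged `"no_amplification"`.
#'
#' @param path Path to the CSV file.
#' @param control A [refstab_control()] object.
#' @return A `data.frame` of reaction records with columns `line`, `organ`,
#'   `stage`, `bio_rep`, `tech_rep`, `gene`, `ct`, `efficiency`, `qc_flags`.
#' @export
read_reactions <- function(path, control = refstab_control()) {
  if (!file.exists(path)) stop("reaction table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character())
  missing_cols <- setdiff(.reaction_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("reaction table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0) stop("reaction table contains no rows")
  parse_num <- function(x) suppressWarnings(as.numeric(x))

  ct_chr <- trimws(raw$ct)
  ct <- parse_num(ct_chr)
  ct_missing <- ct_chr %in% c("NA", "")
  bad_ct <- which(!ct_missing & is.na(ct))
  if (length(bad_ct) > 0) {
    stop("unparseable ct value(s) at row(s) ",
         paste(bad_ct, collapse = ", "), ": ",
         paste(unique(ct_chr[bad_ct]), collapse = ", "))
  }
  bad_pos <- which(!is.na(ct) & ct <= 0)
  if (length(bad_pos) > 0) {
    stop("non-positive ct value(s) at row(s) ", paste(bad_pos, collapse = ", "))
  }

  if ("efficiency" %in% names(raw)) {
    eff_chr <- trimws(raw$efficiency)
    efficiency <- parse_num(eff_chr)
    bad_eff <- which(!(eff_chr %in% c("NA", "")) & is.na(efficiency))
    if (length(bad_eff) > 0) {
      stop("unparseable efficiency value(s) at row(s) ",
           paste(bad_eff, collapse = ", "))
    }
    out_of_range <- which(!is.na(efficiency) &
                            (efficiency <= 1 | efficiency > 2))
    if (length(out_of_range) > 0) {
      stop("efficiency outside (1, 2] at row(s) ",
           paste(out_of_range, collapse = ", "))
    }
  } else if (control$efficiency_mode == "fixed") {
    efficiency <- rep(control$fixed_efficiency, n)
  } else {
    stop("efficiency column absent but efficiency_mode = '",
         control$efficiency_mode, "' requires per-reaction values")
  }

  bio_rep <- parse_num(raw$bio_rep)
  tech_rep <- parse_num(raw$tech_rep)
  if (any(is.na(bio_rep)) || any(bio_rep < 1) || any(bio_rep != round(bio_rep)))
    stop("bio_rep must be a positive integer in every row")
  if (any(is.na(tech_rep)) || any(tech_rep < 1) || any(tech_rep != round(tech_rep)))
    stop("tech_rep must be a positive integer in every row")

  rec <- data.frame(line = raw$line, organ = raw$organ, stage = raw$stage,
                    bio_rep = as.integer(bio_rep),
                    tech_rep = as.integer(tech_rep),
                    gene = raw$gene, ct = ct, efficiency = efficiency,
                    qc_flags = ifelse(is.na(ct), "no_amplification", ""),
                    stringsAsFactors = FALSE)
  key <- with(rec, paste(line, organ, stage, bio_rep, tech_rep, gene, sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate reaction identity at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  rec
}

#' Write a qPCR reaction table
#'
#' Inverse of [read_reactions()]: writes the single supported CSV dialect
#' (comma-separated, `.` decimal, literal `NA`). Numeric fields are written
#' with enough digits for a lossless round trip at 6 decimals.
#'
#' @param reactions A reaction `data.frame` as returned by [read_reactions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(reactions, path) {
  out <- reactions
  out$ct <- ifelse(is.na(out$ct), "NA", formatC(out$ct, format = "f", digits = 6))
  out$efficiency <- ifelse(is.na(out$efficiency), "NA",
                           formatC(out$efficiency, format = "f", digits = 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read amplification curves
#'
#' Reads per-well fluorescence-by-cycle series from a CSV with columns `well`,
#' `cycle`, `fluorescence`. Cycles within each well must form a contiguous
#' integer range starting at 1; rows may appear in any order.
#'
#' @param path Path to the curve CSV.
#' @return A named list of numeric fluorescence vectors, one per well, indexed
#'   by cycle.
#' @seealso [read_wellmap()], [call_ct()], [estimate_efficiency()]
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("curve table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "cycle", "fluorescence")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("curve table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  split_rows <- split(raw, raw$well)
  curves <- lapply(names(split_rows), function(w) {
    d <- split_rows[[w]]
    if (anyDuplicated(d$cycle)) {
      stop("duplicate (well, cycle) entries for well ", w)
    }
    d <- d[order(d$cycle), ]
    if (!identical(as.integer(d$cycle), seq_len(nrow(d)))) {
      stop("cycles for well ", w,
           " are not a contiguous integer range starting at 1")
    }
    as.numeric(d$fluorescence)
  })
  names(curves) <- names(split_rows)
  curves
}

#' Read a well map
#'
#' Binds instrument wells to their sample identity and gene. Columns: `well`,
#' `line`, `organ`, `stage`, `bio_rep`, `tech_rep`, `gene`.
#'
#' @param path Path to the well-map CSV.
#' @return A `data.frame` keyed by `well`.
#' @export
read_wellmap <- function(path) {
  if (!file.exists(path)) stop("well map not found: ", path)
  wm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "line", "organ", "stage", "bio_rep", "tech_rep", "gene")
  missing_cols <- setdiff(need, names(wm))
  if (length(missing_cols) > 0) {
    stop("well map is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(wm$well)) stop("duplicate wells in well map")
  wm
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); blank lines and
#' lines starting with `#` are ignored. Recognised keys are the arguments of
#' [refstab_control()]; numeric-looking values are converted.
#'
#' @param path Path to the configuration file.
#' @return A [refstab_control()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad) > 0) stop("unparseable config line(s): ",
                            paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(refstab_control))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) stop("unknown config key(s): ",
                                paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (v %in% c("TRUE", "FALSE", "true", "false")) return(toupper(v) == "TRUE")
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) return(num)
    v
  })
  names(args) <- keys
  do.call(refstab_control, args)
}

#' @export
print.refstab_control <- function(x, ...) {
  cat("refstab control parameters:\n")
  for (nm in setdiff(names(x), "ce_params")) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
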