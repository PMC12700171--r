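# Descriptor construction and dataset IO.
#
# File schema (UTF-8 CSV, header row):
#   sensitizer table: sensitizer_id, k_r_S1S0, k_ic_S1S0, k_isc_S1T1,
#     k_risc_T1S1, k_isc_T1S0, E_HOMO_eV, E_LUMO_eV, E_S1_eV, E_T1_eV,
#     dEST_eV, f_S1, dDM_debye (+ optional pass-through columns, e.g.
#     measured lifetimes LT_* or decoy_*).
#   reactions table: sensitizer_id, reaction_id, yield_percent.

AUX_NAMES <- c("E_HOMO", "E_LUMO", "E_S1", "E_T1", "dEST", "f_S1", "dDM")

AUX_COLUMN_MAP <- c(E_HOMO = "E_HOMO_eV", E_LUMO = "E_LUMO_eV",
                    E_S1 = "E_S1_eV", E_T1 = "E_T1_eV", dEST = "dEST_eV",
                    f_S1 = "f_S1", dDM = "dDM_debye")

SENSITIZER_COLUMNS <- c("sensitizer_id", RATE_NAMES, unname(AUX_COLUMN_MAP))

SCALED_NAMES <- paste0("s_", RATE_NAMES)

# floor applied to rates before log10: computed reverse-ISC rates can
# underflow to ~1e-5 1/s and below for large singlet-triplet gaps
RATE_LOG_FLOOR <- 1e-12

#' Sum-normalized rate-constant descriptors (s_RC)
#'
#' Expresses the five excited-state rate constants as ratios: each rate is
#' divided by the sum of all five, so the components are dimensionless,
#' lie in \[0, 1\] and sum to one. Branching ratios of this kind put rates
#' spanning ten decades on a common competitive footing.
#'
#' @param rates a [rate_constant_set()] or a named numeric vector/list
#'   containing the five `k_*` rates.
#' @return Named numeric vector of class `scaled_rates` with components
#'   `s_k_r_S1S0`, ..., `s_k_isc_T1S0`.
#' @examples
#' scale_rates(rate_constant_set(k_r_S1S0 = 2.0e7, k_ic_S1S0 = 4.46e4,
#'                               k_isc_S1T1 = 2.6e7, k_risc_T1S1 = 5.3e1,
#'                               k_isc_T1S0 = 3.6e5))
#' @export
scale_rates <- function(rates) {
  rates <- as_rate_constant_set(rates)
  k <- unlist(rates[RATE_NAMES])
  total <- sum(k)
  if (total <= 0) stop("cannot scale an all-zero rate set", call. = FALSE)
  s <- k / total
  names(s) <- SCALED_NAMES
  class(s) <- "scaled_rates"
  s
}

#' Electronic descriptors of one sensitizer
#'
#' The seven ground/excited-state electronic quantities used as auxiliary
#' yield-prediction descriptors: frontier orbital energies, vertical S1 and
#' T1 excitation energies, the vertical singlet-triplet gap, the oscillator
#' strength of the lowest singlet excitation, and the ground-to-excited
#' state dipole moment difference.
#'
#' @param E_HOMO,E_LUMO frontier orbital energies, eV (`E_HOMO < E_LUMO`).
#' @param E_S1,E_T1 vertical excitation energies, eV (`E_T1 <= E_S1`).
#' @param delta_E_ST vertical gap, eV; defaults to `E_S1 - E_T1` and must
#'   agree with it within 1e-6 eV when all are given.
#' @param f_S1 oscillator strength (>= 0).
#' @param delta_DM dipole-moment difference, Debye (>= 0).
#' @return Named list of class `electronic_descriptors`.
#' @export
electronic_descriptors <- function(E_HOMO, E_LUMO, E_S1, E_T1,
                                   delta_E_ST = E_S1 - E_T1, f_S1,
                                   delta_DM) {
  if (E_HOMO >= E_LUMO) stop("E_HOMO must be < E_LUMO", call. = FALSE)
  if (E_T1 > E_S1) stop("E_T1 must be <= E_S1", call. = FALSE)
  if (abs(delta_E_ST - (E_S1 - E_T1)) > 1e-6) {
    stop("delta_E_ST inconsistent with E_S1 - E_T1", call. = FALSE)
  }
  if (f_S1 < 0) stop("f_S1 must be >= 0", call. = FALSE)
  if (delta_DM < 0) stop("delta_DM must be >= 0", call. = FALSE)
  structure(list(E_HOMO = E_HOMO, E_LUMO = E_LUMO, E_S1 = E_S1, E_T1 = E_T1,
                 delta_E_ST = delta_E_ST, f_S1 = f_S1, delta_DM = delta_DM),
            class = "electronic_descriptors")
}

#' Feature-set specification
#'
#' Declares which descriptors enter the model matrix: a base rate-constant
#' set (`"RC"` raw rates, `"s_RC"` sum-normalized ratios, `"lifetime"`
#' pass-through measured-lifetime columns, or `"none"`), a subset of the
#' seven auxiliary electronic descriptors, optional extra pass-through
#' columns (e.g. decoys), and the one-hot reaction encoding flag. Raw RC
#' rates are log10-transformed by default (they span more than ten
#' decades); `s_RC` ratios are never log-transformed.
#'
#' @param base_set one of `"s_RC"`, `"RC"`, `"none"`, `"lifetime"`.
#' @param auxiliary character subset of
#'   `c("E_HOMO","E_LUMO","E_S1","E_T1","dEST","f_S1","dDM")`.
#' @param include_reaction_onehot append one-hot `reaction_<id>` columns
#'   (all levels kept; no reference level dropped).
#' @param rate_transform `"log10"` or `"raw"`, applied to RC columns only.
#' @param extra names of extra pass-through sensitizer-table columns.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(base_set = c("s_RC", "RC", "none", "lifetime"),
                         auxiliary = character(),
                         include_reaction_onehot = TRUE,
                         rate_transform = c("log10", "raw"),
                         extra = character()) {
  base_set <- match.arg(base_set)
  rate_transform <- match.arg(rate_transform)
  auxiliary <- as.character(auxiliary)
  bad <- setdiff(auxiliary, AUX_NAMES)
  if (length(bad) > 0) {
    stop("unknown auxiliary descriptor(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(AUX_NAMES, collapse = ", "),
         call. = FALSE)
  }
  structure(list(base_set = base_set, auxiliary = auxiliary,
                 include_reaction_onehot = isTRUE(include_reaction_onehot),
                 rate_transform = rate_transform,
                 extra = as.character(extra)),
            class = "feature_spec")
}

feature_spec_label <- function(spec) {
  parts <- c(if (spec$base_set != "none") spec$base_set,
             spec$auxiliary, spec$extra)
  paste(parts, collapse = " + ")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec>", feature_spec_label(x),
      if (x$include_reaction_onehot) "+ reaction one-hot", "\n")
  cat("  rate_transform:", x$rate_transform, "\n")
  invisible(x)
}

validate_sensitizer_table <- function(sens) {
  missing_cols <- setdiff(SENSITIZER_COLUMNS, names(sens))
  if (length(missing_cols) > 0) {
    stop("sensitizer table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sens$sensitizer_id)) {
    stop("duplicated sensitizer_id: ",
         paste(unique(sens$sensitizer_id[duplicated(sens$sensitizer_id)]),
               collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(SENSITIZER_COLUMNS, "sensitizer_id")
  for (cl in num_cols) {
    bad <- which(!is.finite(as.numeric(sens[[cl]])))
    if (length(bad) > 0) {
      stop(sprintf("non-finite/malformed numeric in column '%s', row(s) %s",
                   cl, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad <- which(rowSums(as.matrix(sens[RATE_NAMES]) < 0) > 0)
  if (length(bad) > 0) {
    stop("negative rate constant(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(sens)
}

validate_reaction_table <- function(reactions) {
  missing_cols <- setdiff(c("sensitizer_id", "reaction_id", "yield_percent"),
                          names(reactions))
  if (length(missing_cols) > 0) {
    stop("reactions table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(reactions$yield_percent)
  bad <- which(!is.finite(y) | y < 0 | y > 100)
  if (length(bad) > 0) {
    stop("yield_percent outside [0, 100] (or malformed) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(reactions$sensitizer_id, reactions$reaction_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (sensitizer_id, reaction_id) pair(s) in row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(reactions)
}

#' Read a sensitizer/reaction dataset from CSV files
#'
#' @param sensitizer_path,reaction_path CSV paths following the documented
#'   schema (see the package README); unknown extra columns in the
#'   sensitizer table are preserved as pass-through (e.g. measured
#'   lifetime columns `LT_*`).
#' @return List with tibbles `sensitizers` and `reactions`.
#' @export
read_dataset <- function(sensitizer_path, reaction_path) {
  sens <- readr::read_csv(sensitizer_path, show_col_types = FALSE,
                          progress = FALSE)
  reactions <- readr::read_csv(reaction_path, show_col_types = FALSE,
                               progress = FALSE)
  validate_sensitizer_table(sens)
  validate_reaction_table(reactions)
  list(sensitizers = sens, reactions = reactions)
}

#' Write a sensitizer/reaction dataset to CSV files
#'
#' Values are written in shortest round-trip decimal representation, so a
#' write/read cycle reproduces them exactly.
#'
#' @param sensitizers,reactions tibbles following the documented schema.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(sensitizers, reactions, dir, prefix = "dataset") {
  validate_sensitizer_table(sensitizers)
  validate_reaction_table(reactions)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, paste0(prefix, "_sensitizers.csv"))
  rp <- file.path(dir, paste0(prefix, "_reactions.csv"))
  readr::write_csv(sensitizers, sp, progress = FALSE)
  readr::write_csv(reactions, rp, progress = FALSE)
  invisible(c(sensitizers = sp, reactions = rp))
}

#' Assemble the model matrix from a dataset and a feature spec
#'
#' Joins per-sensitizer descriptors onto the (sensitizer, reaction, yield)
#' rows: the base rate-constant block (raw RC columns are floored at
#' 1e-12 1/s and log10-transformed by default, and gain a `log10_` prefix;
#' s_RC ratios are used as-is), the requested auxiliary electronic
#' descriptors, any extra pass-through columns, and one-hot
#' `reaction_<id>` columns.
#'
#' @param reactions reactions tibble (`sensitizer_id`, `reaction_id`,
#'   `yield_percent`).
#' @param sensitizers sensitizer descriptor tibble.
#' @param spec a [feature_spec()].
#' @return Object of class `descriptor_matrix`: list with `features`
#'   (numeric tibble), `target` (yields), `row_ids` and `spec`.
#' @export
assemble_features <- function(reactions, sensitizers, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  validate_sensitizer_table(sensitizers)
  validate_reaction_table(reactions)

  unknown <- setdiff(unique(reactions$sensitizer_id),
                     sensitizers$sensitizer_id)
  if (length(unknown) > 0) {
    stop("reaction rows reference unknown sensitizer_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  rates <- as.matrix(sensitizers[RATE_NAMES])
  base <- switch(spec$base_set,
    RC = {
      m <- rates
      if (spec$rate_transform == "log10") {
        m <- log10(pmax(m, RATE_LOG_FLOOR))
        colnames(m) <- paste0("log10_", RATE_NAMES)
      }
      tibble::as_tibble(m)
    },
    s_RC = {
      m <- rates / rowSums(rates)
      colnames(m) <- SCALED_NAMES
      tibble::as_tibble(m)
    },
    lifetime = {
      lt_cols <- grep("^LT_", names(sensitizers), value = TRUE)
      if (length(lt_cols) == 0) {
        stop("base_set 'lifetime' requires LT_* columns in the sensitizer ",
             "table; none found", call. = FALSE)
      }
      sensitizers[lt_cols]
    },
    none = tibble::tibble(.rows = nrow(sensitizers))
  )

  need_cols <- c(unname(AUX_COLUMN_MAP[spec$auxiliary]), spec$extra)
  missing_cols <- setdiff(need_cols, names(sensitizers))
  if (length(missing_cols) > 0) {
    stop("descriptor column(s) required by the feature spec are missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  aux <- sensitizers[unname(AUX_COLUMN_MAP[spec$auxiliary])]
  if (ncol(aux) > 0) names(aux) <- spec$auxiliary
  extra <- sensitizers[spec$extra]

  per_sens <- dplyr::bind_cols(
    sensitizers["sensitizer_id"], base, aux, extra)
  joined <- dplyr::left_join(reactions, per_sens, by = "sensitizer_id")

  feats <- joined[setdiff(names(per_sens), "sensitizer_id")]
  if (spec$include_reaction_onehot) {
    levels_r <- sort(unique(reactions$reaction_id))
    onehot <- lapply(levels_r,
                     function(r) as.numeric(joined$reaction_id == r))
    names(onehot) <- paste0("reaction_", levels_r)
    feats <- dplyr::bind_cols(feats, tibble::as_tibble(onehot))
  }

  not_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric feature column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  na_cols <- names(feats)[vapply(feats, anyNA, logical(1))]
  if (length(na_cols) > 0) {
    stop("missing values after assembly in column(s): ",
         paste(na_cols, collapse = ", "), call. = FALSE)
  }

  structure(list(features = feats,
                 target = as.numeric(joined$yield_percent),
                 row_ids = joined[c("sensitizer_id", "reaction_id")],
                 spec = spec),
            class = "descriptor_matrix")
}

#' Build a descriptor matrix from a bare feature table
#'
#' Escape hatch for modelling arbitrary numeric features (externally
#' computed descriptors, toy problems) with the same training/evaluation/
#' attribution machinery as [assemble_features()] output.
#'
#' @param features numeric matrix or data frame with named columns.
#' @param target numeric target vector (one value per row).
#' @param row_ids optional tibble of row identifiers (`sensitizer_id`,
#'   `reaction_id`).
#' @return Object of class `descriptor_matrix`.
#' @export
as_descriptor_matrix <- function(features, target, row_ids = NULL) {
  features <- tibble::as_tibble(as.data.frame(features))
  stopifnot(length(target) == nrow(features), !is.null(names(features)))
  if (is.null(row_ids)) {
    row_ids <- tibble::tibble(
      sensitizer_id = sprintf("row%04d", seq_len(nrow(features))),
      reaction_id = "r")
  }
  structure(list(features = features, target = as.numeric(target),
                 row_ids = row_ids, spec = feature_spec("none")),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d rows x %d features (%s)\n",
              nrow(x$features), ncol(x$features), feature_spec_label(x$spec)))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$features)

#' @export
as.matrix.descriptor_matrix <- function(x, ...) {
  m <- as.matrix(x$features)
  rownames(m) <- paste(x$row_ids$sensitizer_id, x$row_ids$reaction_id,
                       sep = "|")
  m
}

# row-subset a descriptor_matrix
dm_subset <- function(dm, rows) {
  structure(list(features = dm$features[rows, , drop = FALSE],
                 target = dm$target[rows],
                 row_ids = dm$row_ids[rows, , drop = FALSE],
                 spec = dm$spec),
            class = "descriptor_matrix")
}
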