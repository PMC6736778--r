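#' Construct a diet specification
#'
#' A diet maps exchange-compound identifiers (compound base names such as
#' `arg`, `glc`) to uptake amounts available to the community, in mmol per
#' gram microbiota per day, plus the caloric value of the recorded intake.
#'
#' @param amounts named non-negative numeric vector (mmol/gM/d).
#' @param participant_id participant identifier.
#' @param caloric_value_kJ caloric value of the diet (kJ/day).
#' @return object of class `diet_spec`.
#' @export
diet_spec <- function(amounts = numeric(), participant_id = NA_character_,
                      caloric_value_kJ = NA_real_) {
  amounts <- unlist(amounts)
  if (length(amounts)) {
    if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
      stop("diet amounts must be named by compound")
    if (any(amounts < 0)) stop("diet amounts must be >= 0")
    amounts <- tapply(amounts, names(amounts), sum)
    amounts <- setNames(as.numeric(amounts), names(amounts))
    amounts <- amounts[order(names(amounts))]
  }
  structure(list(participant_id = participant_id, amounts = amounts,
                 caloric_value_kJ = caloric_value_kJ), class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s: %d compounds, total %.4g mmol/gM/d, %.4g kJ\n",
              x$participant_id, length(x$amounts), sum(x$amounts),
              x$caloric_value_kJ))
  invisible(x)
}

#' Convert a dietary mass to a microbiota-normalised exchange flux
#'
#' Grams per day are converted to millimoles using the molecular weight and
#' divided by the total wet weight of the colonic microbiota (200 g) to give
#' the amount available per gram of microbiota per day:
#' `(grams / mw) * 1000 / microbiota_mass`.
#'
#' @param grams intake in g/day (>= 0).
#' @param mw molecular weight in g/mol (> 0).
#' @param microbiota_mass total microbiota wet weight in g (default 200).
#' @return flux in mmol/gM/d.
#' @export
#' @examples
#' mass_to_flux(36, 180)  # 200 mmol/day over 200 g -> 1 mmol/gM/d
mass_to_flux <- function(grams, mw, microbiota_mass = 200) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  if (microbiota_mass <= 0) stop("microbiota mass must be > 0")
  (grams / mw) * 1000 / microbiota_mass
}

#' Normalise a diet to a target caloric value
#'
#' Every amount is scaled by `target_kJ / caloric_value_kJ`, making diets
#' comparable across participants; the default target is the cohort median
#' caloric value of 8799 kJ.
#'
#' @param diet a `diet_spec` with positive `caloric_value_kJ`.
#' @param target_kJ target caloric value (kJ/day).
#' @return the normalised `diet_spec` (idempotent once at target).
#' @export
normalize_caloric <- function(diet, target_kJ = 8799) {
  if (!is.finite(diet$caloric_value_kJ) || diet$caloric_value_kJ <= 0) {
    stop("diet caloric value must be positive to normalise")
  }
  f <- target_kJ / diet$caloric_value_kJ
  diet$amounts <- diet$amounts * f
  diet$caloric_value_kJ <- target_kJ
  diet
}

# impute per-item contents from a table with a group-average fallback along
# the food-group hierarchy (innermost group first, then parents, then global)
.lookup_content <- function(items, group_paths, table, cols) {
  key <- table[[1]]
  out <- matrix(NA_real_, length(items), length(cols),
                dimnames = list(NULL, cols))
  for (cn in cols) {
    vals <- table[[cn]][match(items, key)]
    miss <- which(is.na(vals))
    for (i in miss) {
      parts <- strsplit(group_paths[i], "/", fixed = TRUE)[[1]]
      for (lvl in rev(seq_along(parts))) {
        prefix <- paste(parts[seq_len(lvl)], collapse = "/")
        sib <- items != items[i] & startsWith(group_paths, prefix)
        pool <- table[[cn]][match(unique(items[sib]), key)]
        pool <- pool[!is.na(pool)]
        if (length(pool)) { vals[i] <- mean(pool); break }
      }
      if (is.na(vals[i])) {
        stop("no ", cn, " data at any hierarchy level for food group '",
             group_paths[i], "'")
      }
    }
    out[, cn] <- vals
  }
  out
}

#' Augment a diet with nucleotides extrapolated from purine contents
#'
#' Purine contents of the consumed food items (mmol adenosine-class and
#' guanosine-class purines per gram food) are summed over the food record,
#' microbiota-normalised, and added to the diet. Pyrimidines, for which no
#' food-content data exist, are extrapolated: thymidine plus uracil together
#' equal the adenosine-class total (split 50/50 by default) and cytosine
#' equals the guanosine-class total. Items missing from the table are imputed
#' with the average of their food group, walking up the group hierarchy.
#'
#' @param diet a `diet_spec`.
#' @param food_records data.frame with columns `food_item`, `group_path`
#'   (slash-separated hierarchy) and `grams_per_day`.
#' @param table data.frame: `food_item`, `adenosine_class`,
#'   `guanosine_class` (mmol per gram food; NA = unmeasured).
#' @param thymidine_fraction share of the adenosine-class total assigned to
#'   thymidine (remainder to uracil).
#' @param microbiota_mass microbiota wet weight (g) for flux normalisation.
#' @return the augmented `diet_spec` (caloric value unchanged: the added
#'   amounts are calorically negligible trace compounds).
#' @export
augment_nucleotides <- function(diet, food_records, table,
                                thymidine_fraction = 0.5,
                                microbiota_mass = 200) {
  cont <- .lookup_content(food_records$food_item, food_records$group_path,
                          table, c("adenosine_class", "guanosine_class"))
  if (any(cont < 0)) stop("negative purine content in table")
  g <- food_records$grams_per_day
  aden <- sum(g * cont[, "adenosine_class"]) / microbiota_mass
  guan <- sum(g * cont[, "guanosine_class"]) / microbiota_mass
  add <- c(adenosine = aden, guanosine = guan,
           thymidine = thymidine_fraction * aden,
           uracil = (1 - thymidine_fraction) * aden,
           cytosine = guan)
  diet$amounts <- .merge_amounts(diet$amounts, add)
  diet
}

#' Augment a diet with polyamines and extrapolated ornithine
#'
#' Measured cadaverine, putrescine, spermidine and spermine contents (mmol
#' per gram food) are summed over the food record and added to the diet.
#' Ornithine, poorly covered by food tables, is taken from the table when
#' measured for an item and otherwise extrapolated as `ornithine_factor`
#' (default 3.28, the median ornithine-to-polyamine ratio over foods with
#' complete data) times the item's total polyamine content.
#'
#' @inheritParams augment_nucleotides
#' @param table data.frame: `food_item`, `cadaverine`, `putrescine`,
#'   `spermidine`, `spermine` (NA = impute from food group) and `ornithine`
#'   (NA = extrapolate by the factor).
#' @param ornithine_factor ornithine-to-total-polyamine ratio used for items
#'   without measured ornithine.
#' @return the augmented `diet_spec`.
#' @export
augment_polyamines <- function(diet, food_records, table,
                               ornithine_factor = 3.28,
                               microbiota_mass = 200) {
  pa_cols <- c("cadaverine", "putrescine", "spermidine", "spermine")
  if (any(unlist(table[c(pa_cols, "ornithine")]) < 0, na.rm = TRUE)) {
    stop("negative polyamine content in table")
  }
  cont <- .lookup_content(food_records$food_item, food_records$group_path,
                          table, pa_cols)
  g <- food_records$grams_per_day
  add <- setNames(colSums(g * cont) / microbiota_mass, pa_cols)
  # per-item ornithine content: measured when available, otherwise the
  # factor times that item's total polyamine content
  orn_meas <- table$ornithine[match(food_records$food_item, table[[1]])]
  orn <- ifelse(is.na(orn_meas), ornithine_factor * rowSums(cont), orn_meas)
  add <- c(add, ornithine = sum(g * orn) / microbiota_mass)
  diet$amounts <- .merge_amounts(diet$amounts, add)
  diet
}

.merge_amounts <- function(a, b) {
  all_names <- union(names(a), names(b))
  out <- setNames(numeric(length(all_names)), all_names)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[order(names(out))]
}

#' Blend a participant diet with a reference (Western) diet
#'
#' Every compound amount becomes
#' `participant_fraction * participant + (1 - participant_fraction) *
#' reference` (default 90% recorded / 10% reference), except compounds on
#' the retained list (growth-limiting minerals such as phosphate, copper,
#' manganese, zinc, iron(3+) and chloride), which keep the reference value
#' unchanged.
#'
#' @param diet participant `diet_spec`.
#' @param reference_diet reference `diet_spec` or named numeric vector.
#' @param participant_fraction weight on the recorded diet, in \[0, 1\].
#' @param retained_compounds compounds taking the reference value as-is.
#' @return the blended `diet_spec`.
#' @export
blend_with_reference <- function(diet, reference_diet,
                                 participant_fraction = 0.9,
                                 retained_compounds = character()) {
  stopifnot(participant_fraction >= 0, participant_fraction <= 1)
  ref <- if (inherits(reference_diet, "diet_spec")) reference_diet$amounts
         else reference_diet
  all_names <- union(names(diet$amounts), names(ref))
  p <- setNames(numeric(length(all_names)), all_names)
  r <- p
  p[names(diet$amounts)] <- diet$amounts
  r[names(ref)] <- ref
  out <- participant_fraction * p + (1 - participant_fraction) * r
  keep <- intersect(retained_compounds, all_names)
  out[keep] <- r[keep]
  diet$amounts <- out[order(names(out))]
  diet
}

#' Remove the host-absorbed fraction of each dietary compound
#'
#' Models the small-intestinal absorption of nutrients before they reach the
#' colonic community: `amount := amount * (1 - absorbed_fraction)`.
#' Compounds absent from the map are unchanged.
#'
#' @param diet a `diet_spec`.
#' @param absorbed_fraction named numeric vector of fractions in \[0, 1\].
#' @return the adjusted `diet_spec`.
#' @export
adjust_absorption <- function(diet, absorbed_fraction) {
  if (any(absorbed_fraction < 0 | absorbed_fraction > 1)) {
    stop("absorbed fractions must lie in [0, 1]")
  }
  hit <- intersect(names(diet$amounts), names(absorbed_fraction))
  diet$amounts[hit] <- diet$amounts[hit] * (1 - absorbed_fraction[hit])
  diet
}

#' Build a participant-specific diet from food-frequency records
#'
#' Runs the full derivation pipeline: map recorded food compounds to
#' exchange compounds and convert masses to microbiota-normalised fluxes;
#' augment with nucleotides and polyamines; normalise to the target caloric
#' value; blend with the reference diet; optionally subtract host
#' absorption. A provenance log (one row per step: total mmol, caloric
#' value, compound count) is attached as attribute `"provenance"`.
#'
#' @param records food records for one participant (`food_item`,
#'   `group_path`, `grams_per_day`; an optional `participant_id` column must
#'   be homogeneous).
#' @param compound_map data.frame `compound`, `exchange_id`,
#'   `molecular_weight` (g/mol, required > 0), `kJ_per_gram`. Recorded food
#'   items found in this map contribute mass to their exchange compound;
#'   other items contribute only through the augmentation tables.
#' @param purine_table,polyamine_table augmentation tables (NULL skips the
#'   step); see [augment_nucleotides()] and [augment_polyamines()].
#' @param reference_diet reference diet for blending (NULL skips).
#' @param absorption named absorbed-fraction vector (NULL skips).
#' @param target_kJ caloric normalisation target (default 8799 kJ).
#' @param participant_fraction,retained_compounds blending parameters.
#' @param ornithine_factor,thymidine_fraction augmentation parameters.
#' @param microbiota_mass microbiota wet weight in g (default 200).
#' @return a `diet_spec` with attribute `"provenance"`.
#' @export
build_participant_diet <- function(records, compound_map,
                                   purine_table = NULL,
                                   polyamine_table = NULL,
                                   reference_diet = NULL,
                                   absorption = NULL,
                                   target_kJ = 8799,
                                   participant_fraction = 0.9,
                                   retained_compounds = character(),
                                   ornithine_factor = 3.28,
                                   thymidine_fraction = 0.5,
                                   microbiota_mass = 200) {
  pid <- if (!is.null(records$participant_id)) {
    u <- unique(records$participant_id)
    if (length(u) > 1) stop("records mix participants: ",
                            paste(u, collapse = ", "))
    u
  } else NA_character_
  if (any(records$grams_per_day < 0)) stop("grams_per_day must be >= 0")

  hit <- match(records$food_item, compound_map$compound)
  mapped <- which(!is.na(hit))
  mw <- compound_map$molecular_weight[hit[mapped]]
  if (any(!is.finite(mw) | mw <= 0)) {
    stop("missing or non-positive molecular weight for mapped compound(s): ",
         paste(unique(records$food_item[mapped][!is.finite(mw) | mw <= 0]),
               collapse = ", "))
  }
  flux <- mass_to_flux(records$grams_per_day[mapped], mw, microbiota_mass)
  kJg <- compound_map$kJ_per_gram[hit[mapped]]
  kJg[is.na(kJg)] <- 0
  caloric <- sum(records$grams_per_day[mapped] * kJg)
  amounts <- tapply(flux, compound_map$exchange_id[hit[mapped]], sum)
  diet <- diet_spec(setNames(as.numeric(amounts), names(amounts)),
                    participant_id = pid, caloric_value_kJ = caloric)

  log <- list(.log_step(diet, "map_and_convert"))
  if (!is.null(purine_table)) {
    diet <- augment_nucleotides(diet, records, purine_table,
                                thymidine_fraction, microbiota_mass)
    log <- c(log, list(.log_step(diet, "augment_nucleotides")))
  }
  if (!is.null(polyamine_table)) {
    diet <- augment_polyamines(diet, records, polyamine_table,
                               ornithine_factor, microbiota_mass)
    log <- c(log, list(.log_step(diet, "augment_polyamines")))
  }
  if (!is.null(target_kJ)) {
    diet <- normalize_caloric(diet, target_kJ)
    log <- c(log, list(.log_step(diet, "normalize_caloric")))
  }
  if (!is.null(reference_diet)) {
    diet <- blend_with_reference(diet, reference_diet, participant_fraction,
                                 retained_compounds)
    log <- c(log, list(.log_step(diet, "blend_with_reference")))
  }
  if (!is.null(absorption)) {
    diet <- adjust_absorption(diet, absorption)
    log <- c(log, list(.log_step(diet, "adjust_absorption")))
  }
  attr(diet, "provenance") <- do.call(rbind, log)
  diet
}

.log_step <- function(diet, step) {
  data.frame(step = step, total_mmol = sum(diet$amounts),
             caloric_kJ = diet$caloric_value_kJ,
             n_compounds = length(diet$amounts), stringsAsFactors = FALSE)
}

#' Build diets for a whole cohort
#'
#' Applies [build_participant_diet()] per participant. When `target_kJ` is
#' NULL the cohort's median pre-normalisation caloric value is used as the
#' normalisation target (the derivation used 8799 kJ, its cohort median);
#' the realised median is reported in the attached `"cohort_log"`.
#'
#' @param records food records for all participants (must carry
#'   `participant_id`).
#' @param ... passed to [build_participant_diet()].
#' @param target_kJ numeric target, or NULL for the cohort median.
#' @return named list of `diet_spec`s with attribute `"cohort_log"`.
#' @export
build_cohort_diets <- function(records, ..., target_kJ = 8799) {
  by_p <- split(records, records$participant_id)
  raw <- lapply(by_p, build_participant_diet, ..., target_kJ = NULL)
  pre_cal <- vapply(raw, `[[`, 0, "caloric_value_kJ")
  tgt <- if (is.null(target_kJ)) median(pre_cal) else target_kJ
  diets <- lapply(by_p, build_participant_diet, ..., target_kJ = tgt)
  attr(diets, "cohort_log") <- list(median_caloric_pre_kJ = median(pre_cal),
                                    target_kJ = tgt,
                                    n_participants = length(diets))
  diets
}

#' Read / write a diet TSV
#'
#' The TSV has columns `compound` and `amount` (mmol/gM/d); comment lines
#' starting with `#` record provenance and are ignored on read.
#'
#' @param path file path.
#' @param diet a `diet_spec` (for writing).
#' @param participant_id id recorded in the returned `diet_spec`.
#' @return [read_diet_tsv()] returns a `diet_spec`; [write_diet_tsv()]
#'   returns `path` invisibly.
#' @export
read_diet_tsv <- function(path, participant_id = NA_character_) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cal <- NA_real_
  hdr <- grep("^# caloric_kJ\t", readLines(path, n = 20), value = TRUE)
  if (length(hdr)) cal <- as.numeric(sub("^# caloric_kJ\t", "", hdr[1]))
  diet_spec(setNames(df$amount, df$compound), participant_id, cal)
}

#' @rdname read_diet_tsv
#' @export
write_diet_tsv <- function(diet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# participant\t%s", diet$participant_id), con)
  writeLines(sprintf("# caloric_kJ\t%.10g", diet$caloric_value_kJ), con)
  prov <- attr(diet, "provenance")
  if (!is.null(prov)) {
    writeLines(sprintf("# step\t%s\ttotal=%.10g", prov$step, prov$total_mmol),
               con)
  }
  writeLines("compound\tamount", con)
  writeLines(sprintf("%s\t%.12g", names(diet$amounts), diet$amounts), con)
  invisible(path)
}
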