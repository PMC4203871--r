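#' Descriptive weight tables of a fitted scorecard
#'
#' The human-readable form of the model: one table of dichotomous features
#' (columns = categories) and one of quartile-discretized features
#' (columns = the four quartile intervals).
#'
#' @param object a fitted `nb_scorecard`.
#' @return list with data.frames `dichotomous` and `quartile`.
#' @export
weight_table <- function(object) {
  stopifnot(inherits(object, "nb_scorecard"))
  dich <- list(); quar <- list()
  for (j in seq_along(object$specs)) {
    sp <- object$specs[[j]]
    w <- object$weights[[j]]
    if (sp$kind == "dichotomous") {
      dich[[length(dich) + 1L]] <- data.frame(
        feature = sp$name, t(w), check.names = FALSE,
        stringsAsFactors = FALSE)
    } else {
      quar[[length(quar) + 1L]] <- data.frame(
        feature = sp$name, t(w), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  empty <- function(cols) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(cols) + 1L))
    names(df) <- c("feature", cols)
    df
  }
  list(
    dichotomous = if (length(dich)) do.call(rbind, dich) else empty(c("no", "yes")),
    quartile = if (length(quar)) do.call(rbind, quar) else empty(c("Q1", "Q2", "Q3", "Q4"))
  )
}

#' Save a scorecard as descriptive tables (JSON)
#'
#' Serializes everything that defines the model: feature specs with their
#' frozen discretizers, the class-conditional counts, class totals,
#' smoothing, priors, and the cached weights. The companion
#' [write_weight_tables()] emits CSV weight tables in the classic
#' feature-by-category layout.
#'
#' @param object a fitted `nb_scorecard`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scorecard <- function(object, path) {
  stopifnot(inherits(object, "nb_scorecard"))
  payload <- list(
    format = "icuscore/nb_scorecard",
    version = 1L,
    features = lapply(object$specs, function(sp) {
      list(name = sp$name, kind = sp$kind, categories = sp$categories,
           edges = sp$edges)
    }),
    counts = lapply(object$counts, function(m) {
      list(adverse = unname(m[, "adverse"]), normal = unname(m[, "normal"]))
    }),
    class_totals = as.list(object$class_totals),
    alpha = object$alpha,
    priors = as.list(object$priors),
    weights = lapply(object$weights, unname)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a scorecard from its descriptive tables
#'
#' Rebuilds the model and verifies its internal consistency: per-feature
#' category counts must sum to the class totals, and the stored weights
#' must equal the weights recomputed from the counts. A table edited by
#' hand that violates either check is rejected with an integrity error.
#'
#' @param path JSON file written by [write_scorecard()].
#' @param tol tolerance for the stored-vs-recomputed weight check.
#' @return an `nb_scorecard`.
#' @export
read_scorecard <- function(path, tol = 1e-8) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(p$format, "icuscore/nb_scorecard")) {
    stop_schema("read_scorecard: not a scorecard file")
  }
  specs <- lapply(p$features, function(f) {
    list(name = f$name, kind = f$kind, categories = f$categories,
         edges = if (length(f$edges)) as.numeric(f$edges) else NULL)
  })
  totals <- c(adverse = as.integer(p$class_totals$adverse),
              normal = as.integer(p$class_totals$normal))
  counts <- lapply(seq_along(p$counts), function(j) {
    m <- cbind(adverse = as.integer(p$counts[[j]]$adverse),
               normal = as.integer(p$counts[[j]]$normal))
    rownames(m) <- specs[[j]]$categories
    m
  })
  names(counts) <- vapply(specs, `[[`, "", "name")
  model <- structure(list(specs = specs, counts = counts,
                          class_totals = totals, alpha = as.numeric(p$alpha),
                          priors = c(adverse = as.numeric(p$priors$adverse),
                                     normal = as.numeric(p$priors$normal)),
                          weights = NULL,
                          prior_term = prior_term(as.numeric(p$priors$adverse),
                                                  as.numeric(p$priors$normal)),
                          call = NULL),
                     class = "nb_scorecard")
  bad_sum <- vapply(counts, function(m) {
    any(abs(colSums(m) - totals) > 0)
  }, logical(1))
  if (any(bad_sum)) {
    stop_data("read_scorecard: integrity error - counts of feature(s) ",
              paste(names(counts)[bad_sum], collapse = ", "),
              " do not sum to the class totals")
  }
  model <- refresh_weights(model)
  stored <- lapply(p$weights, as.numeric)
  for (j in seq_along(stored)) {
    if (max(abs(stored[[j]] - unname(model$weights[[j]]))) > tol) {
      stop_data("read_scorecard: integrity error - stored weights of '",
                specs[[j]]$name, "' disagree with the counts")
    }
  }
  model
}

#' Write CSV weight tables in the feature-by-category layout
#'
#' @param object a fitted `nb_scorecard`.
#' @param dichotomous_path,quartile_path output CSV paths (either may be
#'   `NULL` to skip).
#' @return invisibly, the [weight_table()] list.
#' @export
write_weight_tables <- function(object, dichotomous_path = NULL,
                                quartile_path = NULL) {
  wt <- weight_table(object)
  if (!is.null(dichotomous_path)) {
    utils::write.csv(wt$dichotomous, dichotomous_path, row.names = FALSE)
  }
  if (!is.null(quartile_path)) {
    utils::write.csv(wt$quartile, quartile_path, row.names = FALSE)
  }
  invisible(wt)
}
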