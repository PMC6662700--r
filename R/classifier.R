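# Supervised activity classification: random-forest ensemble over movement
# features, validated on a reserved half of the observer-labelled pings.

ACTIVITY_FEATURES <- c("speed", "turn_angle", "depth", "hour", "port_km", "speed_ma3")
ACTIVITY_LEVELS <- c("fishing", "transit", "port")

#' Train the activity classifier
#'
#' Joins observer activity labels onto movement features, splits the labelled
#' set evenly into training and testing halves (stratified by class), fits a
#' 500-tree random-forest ensemble on the training half and stores the
#' held-out balanced accuracy (fishing vs non-fishing) computed on the
#' reserved testing half.
#'
#' @param features output of [derive_features()].
#' @param labels tibble (vessel_id, timestamp, activity) with activity in
#'   fishing/transit/port; all three classes must be present.
#' @param split training fraction of the labelled set.
#' @param seed integer seed for the split and the forest.
#' @return an `activity_classifier`: the fitted ensemble, the feature list,
#'   `$balanced_accuracy` on the held-out half, and the training seed.
#' @export
train_activity_classifier <- function(features, labels, split = 0.5, seed = 1L) {
  labelled <- dplyr::inner_join(features, labels, by = c("vessel_id", "timestamp"))
  labelled <- labelled[stats::complete.cases(labelled[, ACTIVITY_FEATURES]), ]
  labelled$activity <- factor(labelled$activity, levels = ACTIVITY_LEVELS)
  if (anyNA(labelled$activity)) stop("unknown activity label", call. = FALSE)
  present <- table(labelled$activity)
  if (any(present == 0)) {
    stop("labelled subset must contain all three classes; missing: ",
         paste(names(present)[present == 0], collapse = ", "), call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(base::split(seq_len(nrow(labelled)), labelled$activity), function(ix) {
      sample(ix, max(1L, floor(length(ix) * split)))
    }), use.names = FALSE)
  })
  train <- labelled[idx_train, ]
  test <- labelled[-idx_train, ]
  if (nlevels(droplevels(train$activity)) < 3 || nrow(test) == 0) {
    stop("a class is absent from the training or testing half; need more labels",
         call. = FALSE)
  }
  fit <- ranger::ranger(
    stats::as.formula(paste("activity ~", paste(ACTIVITY_FEATURES, collapse = " + "))),
    data = train, num.trees = 500, seed = seed, num.threads = 1
  )
  pred <- stats::predict(fit, data = test, num.threads = 1)$predictions
  ba <- balanced_accuracy(as.character(test$activity), as.character(pred))
  structure(list(model = fit, features = ACTIVITY_FEATURES,
                 balanced_accuracy = ba, seed = seed,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "activity_classifier")
}

#' Predict activity for feature rows
#'
#' Deterministic given a fitted classifier. Pings within `port_radius_km` of
#' the port are labelled `port` by rule before the ensemble is consulted
#' (dockside records need no model).
#'
#' @param classifier an [train_activity_classifier()] result.
#' @param features feature rows with the same schema used in training.
#' @param port_radius_km radius of the dockside override, km.
#' @return character vector of activity labels, one per row.
#' @export
classify_activity <- function(classifier, features, port_radius_km = 2) {
  stopifnot(inherits(classifier, "activity_classifier"))
  miss <- setdiff(classifier$features, names(features))
  if (length(miss)) {
    stop("features missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) == 0) return(character(0))
  pred <- as.character(stats::predict(classifier$model, data = features,
                                      num.threads = 1)$predictions)
  pred[features$port_km <= port_radius_km] <- "port"
  pred
}

#' Balanced accuracy of fishing detection
#'
#' Collapses labels to fishing vs non-fishing and returns the mean of the
#' true-positive and true-negative rates, so the score is penalized for
#' incorrect labelling of either class.
#'
#' @param truth,predicted equal-length label vectors.
#' @return a number in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length", call. = FALSE)
  pos <- truth == "fishing"
  if (!any(pos) || all(pos)) {
    stop("balanced accuracy undefined: need both fishing and non-fishing truth",
         call. = FALSE)
  }
  tpr <- mean(predicted[pos] == "fishing")
  tnr <- mean(predicted[!pos] != "fishing")
  (tpr + tnr) / 2
}
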