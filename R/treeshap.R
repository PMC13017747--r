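# R-side glue for the compiled TreeSHAP: extract the fitted booster's
# trees into flat arrays and call the double-precision recursion.

# Parse an xgboost booster into per-tree node arrays (0-based indices).
parse_booster_trees <- function(model) {
  stopifnot(inherits(model, "fitted_model"),
            model$spec$name %in% BOOSTED_MODELS)
  dt <- xgboost::xgb.model.dt.tree(model = model$handle)
  df <- as.data.frame(dt)
  value_col <- if ("Gain" %in% names(df)) "Gain" else "Quality"
  trees <- lapply(split(df, df$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    # node numbers need not be consecutive (leaf-wise growth skips ids):
    # children are re-indexed to row positions (0-based)
    pos_of <- function(id) {
      ifelse(is.na(id), -1L, match(id, tr$ID) - 1L)
    }
    leaf <- tr$Feature == "Leaf"
    list(feature = ifelse(leaf, -1L,
                          match(tr$Feature, model$feature_names) - 1L),
         split = ifelse(leaf, 0, tr$Split),
         yes = pos_of(tr$Yes),
         no = pos_of(tr$No),
         missing = pos_of(tr$Missing),
         value = ifelse(leaf, tr[[value_col]], 0),
         cover = tr$Cover)
  })
  trees <- trees[order(as.integer(names(trees)))]
  feat_idx <- unlist(lapply(trees, `[[`, "feature"))
  if (anyNA(feat_idx)) {
    stop("booster splits on a feature absent from the model's feature list",
         call. = FALSE)
  }
  trees <- lapply(trees, function(t) {
    t$feature <- as.integer(t$feature)
    t$yes <- as.integer(t$yes); t$no <- as.integer(t$no)
    t$missing <- as.integer(t$missing)
    t$split <- as.numeric(t$split); t$value <- as.numeric(t$value)
    t$cover <- as.numeric(t$cover)
    t
  })
  cfg <- xgboost::xgb.config(model$handle)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  list(trees = unname(trees), base_offset = stats::qlogis(base_score))
}

tree_shap_matrix <- function(model, X) {
  parsed <- parse_booster_trees(model)
  .treeshap_cpp(parsed$trees, X, length(model$feature_names),
                parsed$base_offset)
}

tree_margin <- function(model, X) {
  parsed <- parse_booster_trees(model)
  as.numeric(.tree_margin_cpp(parsed$trees, X, parsed$base_offset))
}
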