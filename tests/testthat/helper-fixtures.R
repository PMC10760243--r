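## shared fixture builders; everything is generated in code

tiny_grid <- function(dims = c(8, 8, 8), voxel = 3) volume_grid(dims, voxel)

rand_volume <- function(grid = tiny_grid(), seed = 1, kind = NULL) {
  set.seed(seed)
  as_volume(array(stats::rnorm(prod(grid$dims)), grid$dims), grid,
            feature_kind = kind)
}

rand_stack <- function(grid = tiny_grid(), K = 5, seed = 1) {
  set.seed(seed)
  component_stack(array(stats::rnorm(prod(grid$dims) * K),
                        c(grid$dims, K)), grid)
}

## positive volume whose mask keeps everything
unit_volume <- function(grid = tiny_grid(), seed = 1) {
  set.seed(seed)
  as_volume(array(stats::runif(prod(grid$dims), 0.1, 1), grid$dims), grid,
            feature_kind = "smri")
}

## a labelled input with channels drawn uniformly in [0, 1]
rand_input <- function(grid, n_channels, label = "AD", subject_id = "s1",
                       seed = 1) {
  set.seed(seed)
  chans <- lapply(seq_len(n_channels), function(i)
    as_volume(array(stats::runif(prod(grid$dims)), grid$dims), grid))
  neurofuse:::model_input(chans, subject_id = subject_id, label = label,
                          experiment = c("unimodal", "two_channel",
                                         "fused")[n_channels])
}

## small cohort of labelled random inputs for model/training tests
rand_input_set <- function(grid, n_channels, n_per_class = 4, seed = 1) {
  labs <- rep(c("AD", "CN"), each = n_per_class)
  lapply(seq_along(labs), function(i)
    rand_input(grid, n_channels, label = labs[i],
               subject_id = sprintf("s%02d", i), seed = seed + i))
}

small_cnn_config <- function(n_channels = 1, n_classes = 2)
  cnn_config(n_channels, n_classes, conv_filters = c(4L, 8L),
             pool_after = 1L, fc_widths = c(8L, 4L))
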