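# Shared expensive fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

default_scene <- function() {
  if (is.null(.fixtures$scene)) .fixtures$scene <- build_scene()
  .fixtures$scene
}

prepared_scene <- function() {
  if (is.null(.fixtures$prepared))
    .fixtures$prepared <- prepare_stapedioplasty_scene(default_scene())
  .fixtures$prepared
}

# the paired crimping runs of the two-arm experiment (seed fixed)
crimp_runs <- function() {
  if (is.null(.fixtures$crimp)) {
    scene <- prepared_scene()
    traj <- make_crimp_trajectory(scene$tools$forceps$pose0$t, seed = 7)
    single <- run_stapedioplasty(scene, traj)
    dual <- run_stapedioplasty(scene, traj,
                               second_arm = make_blocking_trajectory(scene))
    .fixtures$crimp <- list(single = single, dual = dual)
  }
  .fixtures$crimp
}

# a scripted full-FEM stapedotomy (short plunge)
stapedotomy_run <- function() {
  if (is.null(.fixtures$stap)) {
    scene <- default_scene()
    traj <- make_plunge_trajectory(scene$target_point, duration = 3)
    .fixtures$stap <- run_stapedotomy(scene, traj)
  }
  .fixtures$stap
}
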