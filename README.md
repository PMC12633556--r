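# retwave

Automatic detection and spatiotemporal analysis of **retinal waves** —
the bursts of spontaneous activity that sweep across the retinal
ganglion cell layer before eye opening and instruct the development of
the visual system (retinotopic mapping, eye-specific segregation,
direction selectivity).

`retwave` takes spatiotemporally resolved recordings of neural activity —
spike tables from high-density multielectrode arrays (HD-MEA) with an
electrode map, or calcium-imaging-style x,y,t movies — and:

1. **rasterizes** spikes onto the electrode grid into an x,y,t activity
   movie (default pitch 87.5 µm, 1-s frames);
2. **aligns** recordings into a canonical retinal orientation (temporal
   left, nasal right, ventral bottom, optic nerve centred);
3. separates **phasic from tonic** activity with a dynamic per-pixel
   burst detector (rolling median/MAD baseline), so waves remain
   detectable when baseline firing is pharmacologically elevated;
4. **segments waves by 3D flood fill**: a wave is any maximal cluster of
   phasic pixels connected in space (x, y) *and* time (t); isolated
   active pixels are discarded. The result is a label matrix the same
   size as the recording;
5. **quantifies** each wave and the population.

## The quantities it computes

For a recording with detected waves `k = 1..K`:

- **wave frequency** — per-pixel mean of (distinct waves through the
  pixel)/recording time, in waves·min⁻¹, plus the whole-retina total;
- **inter-wave intervals (IWI)** — minutes between consecutive wave
  onsets at each pixel, pooled across pixels;
- **area** — distinct spatial footprint × pitch² (µm²), a pixel active
  in many frames counts once;
- **duration** — `(t_end − t_start) · frame_s` seconds;
- **speed** — mean Euclidean-distance-transform distance of newly
  recruited leading-edge pixels to the previous frame's footprint, per
  frame pair, × pitch / frame interval (µm/s);
- **initiation site / IBI** — centre of mass of the first frame;
  `IBI = numN / (numN + numT)` over nasal vs temporal halves;
- **flow field / propagation direction / NBI** — per-pixel 3×3
  local-centre-of-mass displacement vectors summed over the wave; the
  mean vector is classified into 90°-wide cardinal bins and
  `NBI = numN / (numN + numT + numV + numD)` (0.25 = no bias);
- **local synchrony index** —
  `LSI = activity_wf / (activity_wf + activity_aheadwf)`, activity on
  the leading wavefront versus just ahead of it (1 = perfectly confined
  wave).

A built-in simulator generates recordings with known ground truth
(planar bands or expanding discs, Poisson wavefront/tonic spiking,
configurable rate, speed, direction and initiation bias), which is how
the whole pipeline is validated end to end.

## Worked example

```r
library(retwave)

params <- wave_preset("1.5wk", duration_s = 900, rng_seed = 7)
sim    <- simulate_recording(params)
movie  <- rasterize(sim$spikes, frame_s = 1)
phasic <- filter_phasic(movie)
waves  <- segment_waves(phasic)
summarize_recording(waves, movie)
```

```
<recording_summary> 37 waves in 15 min
  frequency: 2.236 waves/min/pixel, 2.467 waves/min total
  area 1.777e+06 um^2 | duration 10.16 s | speed 140.9 um/s
  IBI 0.351 | NBI 0.595 | LSI 0.804 | IWI mean 0.441 min (n=8331)
```

The simulated recording contained 38 ground-truth waves; 37 are
detected (one truncated at the recording edge). The `1.5wk` preset
draws nasally biased planar waves, and the recovered propagation bias
(NBI 0.595, against 0.25 for no bias) reflects that; LSI 0.804 reflects
the preset's ahead-of-wavefront noise (expected 1/(1 + 0.25) = 0.8).
Per-wave values are in `summarize_recording(...)$wave_table` (or
`wave_table(waves, movie)`), and `plot(waves)` draws the label montage
or a polar direction histogram.

The same pipeline runs from a config file:

```sh
inst/cli/retwave run --config run.yaml --out outdir/   # or run_pipeline() in R
```

writing `wave_table.csv`, `summary.json`, `labels.h5`/`phasic.h5` (when
rhdf5 is available) and a run log with every parameter.

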