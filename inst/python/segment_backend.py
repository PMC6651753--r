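"""Superpixel segmentation worker.

Reads a JSON job file: {"image": <png path>, "out_dir": <dir>,
"jobs": [{"id": n, "algorithm": ..., <params>}, ...]} and writes each
resulting label raster to <out_dir>/labels_<id>.csv as an integer grid.
Batching several jobs per invocation amortizes interpreter startup during
parameter searches.
"""
import json
import sys

import numpy as np
import imageio.v3 as iio
from skimage.segmentation import felzenszwalb, slic, quickshift
from skimage.util import img_as_float


def run_job(img, job):
    algo = job["algorithm"]
    sigma = float(job.get("sigma", 0.8))
    if algo == "fha":
        return felzenszwalb(img, scale=float(job["scale"]), sigma=sigma)
    if algo == "slic":
        return slic(img, n_segments=int(job["n_segments"]), sigma=sigma,
                    start_label=0)
    if algo == "quickshift":
        return quickshift(img_as_float(img), ratio=float(job["ratio"]),
                          kernel_size=float(job["kernel_size"]),
                          max_dist=float(job["max_dist"]), sigma=sigma,
                          rng=0)
    raise ValueError("unknown algorithm: %s" % algo)


def main():
    with open(sys.argv[1]) as fh:
        spec = json.load(fh)
    img = iio.imread(spec["image"])[:, :, :3]
    for job in spec["jobs"]:
        labels = run_job(img, job)
        out = "%s/labels_%d.csv" % (spec["out_dir"], job["id"])
        np.savetxt(out, labels.astype(int), fmt="%d", delimiter=",")


if __name__ == "__main__":
    main()
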