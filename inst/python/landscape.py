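"""Embedding / density-clustering backend for the conformational landscape.

Reads a plain CSV of feature rows (no header), runs UMAP and/or HDBSCAN and
writes a CSV back. Called by the R package through a subprocess; one process
can serve several seeds to amortise interpreter start-up.
"""
import argparse
import sys
import warnings

import numpy as np


def parse_args(argv):
    p = argparse.ArgumentParser()
    p.add_argument("--features", required=True)
    p.add_argument("--out", required=True)
    p.add_argument("--mode", choices=["embed", "cluster", "pipeline"],
                   required=True)
    p.add_argument("--n-neighbors", type=int, default=15)
    p.add_argument("--min-dist", type=float, default=0.0)
    p.add_argument("--seeds", default="42")
    p.add_argument("--min-cluster-size", type=int, default=10)
    p.add_argument("--min-samples", type=int, default=3)
    p.add_argument("--epsilon", type=float, default=0.2)
    return p.parse_args(argv)


def embed(x, n_neighbors, min_dist, seed):
    import umap
    reducer = umap.UMAP(n_neighbors=n_neighbors, min_dist=min_dist,
                        n_components=2, random_state=seed)
    return reducer.fit_transform(x)


def cluster(emb, min_cluster_size, min_samples, epsilon):
    from sklearn.cluster import HDBSCAN
    model = HDBSCAN(min_cluster_size=min_cluster_size,
                    min_samples=min_samples,
                    cluster_selection_epsilon=epsilon, copy=True)
    return model.fit_predict(emb)


def main(argv):
    a = parse_args(argv)
    warnings.filterwarnings("ignore")
    x = np.loadtxt(a.features, delimiter=",", ndmin=2)
    seeds = [int(s) for s in a.seeds.split(",")]
    rows = []
    if a.mode == "cluster":
        lab = cluster(x, a.min_cluster_size, a.min_samples, a.epsilon)
        rows = [[int(v)] for v in lab]
        header = "label"
    else:
        header = "seed,x,y" if a.mode == "embed" else "seed,x,y,label"
        for seed in seeds:
            emb = embed(x, a.n_neighbors, a.min_dist, seed)
            if a.mode == "pipeline":
                lab = cluster(emb, a.min_cluster_size, a.min_samples,
                              a.epsilon)
                rows += [[seed, e[0], e[1], int(l)]
                         for e, l in zip(emb, lab)]
            else:
                rows += [[seed, e[0], e[1]] for e in emb]
    with open(a.out, "w") as fh:
        fh.write(header + "\n")
        for r in rows:
            fh.write(",".join("%d" % v if isinstance(v, int)
                              else "%.9g" % float(v) for v in r) + "\n")


if __name__ == "__main__":
    main(sys.argv[1:])
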