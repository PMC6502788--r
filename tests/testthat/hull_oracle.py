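"""Independent convex-hull volume oracle (qhull via scipy).

Reads a CSV of points with columns case,x1[,x2[,x3]] on stdin or as argv[1],
prints one line per case: "<case>,<volume>". Degenerate hulls (points not
spanning the full dimensionality) print "NA".
"""
import sys

import numpy as np
from scipy.spatial import ConvexHull

path = sys.argv[1]
data = {}
with open(path) as fh:
    header = fh.readline()
    ncol = len(header.strip().split(",")) - 1
    for line in fh:
        parts = line.strip().split(",")
        if not parts[0]:
            continue
        data.setdefault(parts[0], []).append(
            [float(v) for v in parts[1:] if v != ""])

for case in sorted(data, key=lambda c: int(c)):
    pts = np.unique(np.array(data[case]), axis=0)
    d = pts.shape[1]
    if pts.shape[0] < d + 1 or np.linalg.matrix_rank(pts - pts.mean(0)) < d:
        print(f"{case},NA")
        continue
    if d == 1:
        print(f"{case},{pts.max() - pts.min():.17g}")
        continue
    try:
        hull = ConvexHull(pts)
        print(f"{case},{hull.volume:.17g}")
    except Exception:
        print(f"{case},NA")
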