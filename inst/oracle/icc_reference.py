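"""Independent reference implementation of single-measurement ICCs.

Computes McGraw & Wong ICC(A,1) and ICC(C,1) with F-based confidence
intervals using numpy/scipy, and cross-anchors the point estimates against
pingouin when it is importable (pingouin rounds its reported CIs to two
decimals, so CIs are taken from the scipy arithmetic).

Input: long CSV with columns matrix_id, subject, rater, value.
Output: CSV with one row per (matrix_id, model) carrying icc, ci_low,
ci_high, and the pingouin point estimate (NaN when unavailable).

Usage: python icc_reference.py <in.csv> <out.csv> [alpha]
"""
import sys

import numpy as np
import pandas as pd
from scipy import stats

try:
    import pingouin as pg
except Exception:  # pragma: no cover - pingouin is optional
    pg = None


def mean_squares(m):
    n, k = m.shape
    gm = m.mean()
    rm = m.mean(axis=1)
    cm = m.mean(axis=0)
    msr = k * ((rm - gm) ** 2).sum() / (n - 1)
    msc = n * ((cm - gm) ** 2).sum() / (k - 1)
    resid = m - rm[:, None] - cm[None, :] + gm
    mse = (resid ** 2).sum() / ((n - 1) * (k - 1))
    return msr, msc, mse


def icc_consistency(m, alpha=0.05):
    n, k = m.shape
    msr, msc, mse = mean_squares(m)
    icc = (msr - mse) / (msr + (k - 1) * mse)
    f = msr / mse
    fl = f / stats.f.ppf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu = f * stats.f.ppf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    return icc, (fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)


def icc_absolute(m, alpha=0.05):
    n, k = m.shape
    msr, msc, mse = mean_squares(m)
    icc = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    a = k * icc / (n * (1 - icc))
    b = 1 + k * icc * (n - 1) / (n * (1 - icc))
    nu = (a * msc + b * mse) ** 2 / (
        (a * msc) ** 2 / (k - 1) + (b * mse) ** 2 / ((n - 1) * (k - 1)))
    f1 = stats.f.ppf(1 - alpha / 2, n - 1, nu)
    f2 = stats.f.ppf(1 - alpha / 2, nu, n - 1)
    lo = n * (msr - f1 * mse) / (
        f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi = n * (f2 * msr - mse) / (
        k * msc + (k * n - k - n) * mse + n * f2 * msr)
    return icc, lo, hi


def pingouin_point(df, model):
    if pg is None:
        return float("nan")
    res = pg.intraclass_corr(df, targets="subject", raters="rater",
                             ratings="value").set_index("Type")
    return float(res.loc[model, "ICC"])


def main(argv):
    inp, outp = argv[1], argv[2]
    alpha = float(argv[3]) if len(argv) > 3 else 0.05
    data = pd.read_csv(inp)
    rows = []
    for mid, g in data.groupby("matrix_id"):
        wide = g.pivot(index="subject", columns="rater", values="value")
        m = wide.to_numpy(dtype=float)
        for model, fn, pg_label in (
                ("absolute_agreement", icc_absolute, "ICC(A,1)"),
                ("consistency", icc_consistency, "ICC(C,1)")):
            icc, lo, hi = fn(m, alpha)
            rows.append({
                "matrix_id": mid, "model": model, "icc": icc,
                "ci_low": lo, "ci_high": hi,
                "pingouin_icc": pingouin_point(g, pg_label)})
    pd.DataFrame(rows).to_csv(outp, index=False, float_format="%.15g")


if __name__ == "__main__":
    main(sys.argv)
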