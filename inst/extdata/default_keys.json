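{
  "Extraversion": {"item_count": 12, "response_min": 1, "response_max": 5,
    "reverse_items": [3, 4, 6, 7, 8, 11], "aggregation": "mean",
    "items": [1, 6, 11, 16, 21, 26, 31, 36, 41, 46, 51, 56]},
  "Agreeableness": {"item_count": 12, "response_min": 1, "response_max": 5,
    "reverse_items": [3, 4, 5, 8, 9, 10], "aggregation": "mean",
    "items": [2, 7, 12, 17, 22, 27, 32, 37, 42, 47, 52, 57]},
  "Conscientiousness": {"item_count": 12, "response_min": 1, "response_max": 5,
    "reverse_items": [1, 2, 5, 6, 10, 12], "aggregation": "mean",
    "items": [3, 8, 13, 18, 23, 28, 33, 38, 43, 48, 53, 58]},
  "NegativeEmotionality": {"item_count": 12, "response_min": 1, "response_max": 5,
    "reverse_items": [1, 2, 5, 6, 9, 10], "aggregation": "mean",
    "items": [4, 9, 14, 19, 24, 29, 34, 39, 44, 49, 54, 59]},
  "OpenMindedness": {"item_count": 12, "response_min": 1, "response_max": 5,
    "reverse_items": [1, 5, 6, 9, 10, 11], "aggregation": "mean",
    "items": [5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60]},
  "PSS14": {"item_count": 14, "response_min": 0, "response_max": 4,
    "reverse_items": [4, 5, 6, 7, 9, 10, 13], "aggregation": "sum"}
}
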