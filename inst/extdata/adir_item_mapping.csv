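item_id,domain,subscale,applicable
a1_social_smile,SC,A1,all
a1_offer_comfort,SC,A1,all
a1_shared_enjoyment,SC,A1,all
a1_social_overture_quality,SC,A1,all
a1_reciprocal_conversation,SC,A1,verbal
a1_social_chat,SC,A1,verbal
a2_eye_gaze,SC,A2,all
a2_facial_expression,SC,A2,all
a2_pointing_interest,SC,A2,all
a2_conventional_gestures,SC,A2,all
a2_nodding,SC,A2,all
a3_peer_interest,SC,A3,all
a3_imaginative_play_peers,SC,A3,all
a3_friendships,SC,A3,age5plus
a3_group_play,SC,A3,all
b1_stereotyped_utterances,RRB,B1,verbal
b1_hand_finger_mannerisms,RRB,B1,all
b1_complex_mannerisms,RRB,B1,all
b1_repetitive_object_use,RRB,B1,all
b2_verbal_rituals,RRB,B2,verbal
b2_compulsions_rituals,RRB,B2,all
b2_resistance_change,RRB,B2,all
b3_circumscribed_interests,RRB,B3,all
b3_unusual_preoccupations,RRB,B3,all
b3_unusual_attachments,RRB,B3,all
b4_unusual_sensory_interests,RRB,B4,all
b4_sensitivity_noise,RRB,B4,all
b4_abnormal_pain_response,RRB,B4,all
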